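# GY94-style codon substitution model: equilibrium frequencies, rate matrix,
# transition probabilities, pruning likelihood.

#' F3x4 codon equilibrium frequencies
#'
#' Empirical nucleotide frequencies are tabulated separately at the three
#' codon positions (gaps and masked codons excluded); the frequency of a
#' codon is the product of its three positional nucleotide frequencies,
#' renormalised over the sense codons of the genetic code.
#'
#' @param aln A `codon_alignment`.
#' @return Named numeric vector over sense codons, summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  gc <- genetic_code(aln$code)
  cods <- aln$codons[!is.na(aln$codons)]
  if (length(cods) == 0L) stop("alignment has no usable codons")
  freq <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  for (pos in 1:3) {
    tab <- table(factor(substr(cods, pos, pos), levels = NUC))
    if (sum(tab) == 0) stop("no observed nucleotides at codon position ", pos)
    freq[pos, ] <- tab / sum(tab)
  }
  pi <- vapply(gc$sense, function(cd) {
    freq[1, substr(cd, 1, 1)] * freq[2, substr(cd, 2, 2)] *
      freq[3, substr(cd, 3, 3)]
  }, numeric(1))
  if (sum(pi) == 0) stop("all sense codons have zero F3x4 frequency")
  pi / sum(pi)
}

# Single-nucleotide change structure of the sense-codon space, cached per
# code: index pairs plus transition and nonsynonymous indicators.
codon_change_structure <- function(code) {
  key <- paste0("chg_", code)
  if (!is.null(.ifacevol_cache[[key]])) return(.ifacevol_cache[[key]])
  gc <- genetic_code(code)
  n <- gc$n_state
  from <- integer(); to <- integer(); ts <- logical(); nonsyn <- logical()
  for (i in seq_len(n)) {
    nb <- codon_neighbours(gc$sense[i])
    j <- match(nb$to, gc$sense)
    keep <- !is.na(j)
    from <- c(from, rep.int(i, sum(keep)))
    to <- c(to, j[keep])
    ts <- c(ts, nb$ts[keep])
    nonsyn <- c(nonsyn, gc$aa[nb$to[keep]] != gc$aa[[gc$sense[i]]])
  }
  out <- list(from = from, to = to, ts = ts, nonsyn = nonsyn, n = n)
  .ifacevol_cache[[key]] <- out
  out
}

#' GY94-style codon rate matrix
#'
#' Instantaneous rates are zero for multi-nucleotide changes; a single
#' nucleotide change i -> j has rate proportional to the target codon
#' frequency `pi[j]`, multiplied by `kappa` for transitions and by `omega`
#' for nonsynonymous changes. The generator is scaled so that the expected
#' number of substitutions per codon per unit time at stationarity is 1,
#' making branch lengths interpretable as nucleotide substitutions per
#' codon.
#'
#' @param pi Sense-codon frequencies (e.g. from [f3x4_frequencies()]).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param code Genetic code name.
#' @param normalize If `TRUE` (default), scale to one expected substitution
#'   per codon per unit time; if `FALSE`, return the unnormalised generator
#'   (useful when several omega classes must share a common scale).
#' @return `n_state x n_state` generator matrix (rows sum to zero).
#' @export
gy94_rate_matrix <- function(pi, kappa, omega, code = "vertebrate_mito",
                             normalize = TRUE) {
  if (omega < 0) stop("omega must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  ch <- codon_change_structure(code)
  stopifnot(length(pi) == ch$n)
  Q <- matrix(0, ch$n, ch$n,
              dimnames = list(genetic_code(code)$sense,
                              genetic_code(code)$sense))
  rate <- pi[ch$to] * ifelse(ch$ts, kappa, 1) * ifelse(ch$nonsyn, omega, 1)
  Q[cbind(ch$from, ch$to)] <- rate
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Expected substitutions per codon per unit time of the unnormalised
# generator; the normalisation constant behind branch-length scaling.
gy94_mean_rate <- function(pi, kappa, omega, code = "vertebrate_mito") {
  pf <- pmax(pi, 1e-9); pf <- pf / sum(pf)
  Qu <- gy94_rate_matrix(pf, kappa, omega, code, normalize = FALSE)
  -sum(pf * diag(Qu))
}

# Spectral decomposition of the reversible codon generator, via the
# pi-symmetrised form. Returns factors from which exp(Qt) and restricted
# (labelled) transition integrals are assembled cheaply per branch length.
codon_eigen <- function(pi, kappa, omega, code = "vertebrate_mito",
                        pi_floor = 1e-9, scale_factor = NULL) {
  pf <- pmax(pi, pi_floor)
  pf <- pf / sum(pf)
  Q <- if (is.null(scale_factor))
    gy94_rate_matrix(pf, kappa, omega, code) else
    gy94_rate_matrix(pf, kappa, omega, code, normalize = FALSE) / scale_factor
  sq <- sqrt(pf)
  B <- (sq * Q) %*% diag(1 / sq)  # rows scaled by sqrt(pi), cols by 1/sqrt
  B <- (B + t(B)) / 2             # symmetrise numerical noise
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U = (1 / sq) * e$vectors,        # D^{-1/2} V
       Uinv = t(e$vectors) %*% diag(sq), # V' D^{1/2}
       pi = pf, Q = Q, kappa = kappa, omega = omega, code = code)
}

# Transition probability matrix exp(Qt) from the spectral factors.
prob_matrix <- function(eg, t) {
  P <- eg$U %*% (exp(eg$values * t) * eg$Uinv)
  P[P < 0] <- 0
  P
}

# Integrated nonsynonymous-labelled transition matrix:
# J_ij(t) = int_0^t [exp(Qs) L exp(Q(t-s))]_ij ds, with L the nonsynonymous
# off-diagonal part of Q. Used for conditional expected substitution counts.
labelled_integral <- function(eg, t, label = c("nonsyn", "syn", "all")) {
  label <- match.arg(label)
  ch <- codon_change_structure(eg$code)
  n <- ch$n
  L <- matrix(0, n, n)
  keep <- switch(label, nonsyn = ch$nonsyn, syn = !ch$nonsyn,
                 all = rep(TRUE, length(ch$nonsyn)))
  idx <- cbind(ch$from[keep], ch$to[keep])
  L[idx] <- eg$Q[idx]
  G <- eg$Uinv %*% L %*% eg$U
  lam <- eg$values
  dl <- outer(lam, lam, "-")
  elt <- exp(lam * t)
  Phi <- (outer(elt, elt, "-")) / dl
  same <- abs(dl) < 1e-10
  Phi[same] <- (t * elt[row(Phi)])[same]
  J <- eg$U %*% (G * Phi) %*% eg$Uinv
  J[J < 0] <- 0
  J
}

# --- tree plumbing -----------------------------------------------------------

# Validate and index an ape tree for pruning. Works for rooted or unrooted
# (basal multifurcation) trees; branch lengths must be present and >= 0.
prepare_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips do not match alignment taxa")
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, len = pmax(tr$edge.length, 1e-8),
       ntip = length(tr$tip.label), nnode = tr$Nnode,
       root = length(tr$tip.label) + 1L,
       tip_index = match(tr$tip.label, taxa), tree = tr)
}

# Compress integer state columns (taxa x cols) into unique patterns.
pattern_compress <- function(states) {
  keystr <- apply(states, 2, paste, collapse = "|")
  u <- !duplicated(keystr)
  pat <- states[, u, drop = FALSE]
  w <- as.numeric(table(factor(keystr, levels = keystr[u])))
  list(pat = pat, w = w, map = match(keystr, keystr[u]))
}

# Felsenstein pruning with per-pattern log-scaling. Returns the root
# partial-likelihood matrix, accumulated log scale factors and, optionally,
# per-edge scaled child partials / messages for downstream passes.
prune_pass <- function(tp, Plist, pat, n_state, keep_messages = FALSE) {
  ntot <- tp$ntip + tp$nnode
  npat <- ncol(pat)
  partial <- vector("list", ntot)
  logscale <- matrix(0, 1, npat)
  # tip partials
  for (tip in seq_len(tp$ntip)) {
    M <- matrix(0, n_state, npat)
    st <- pat[tip, ]
    amb <- is.na(st)
    if (any(!amb)) M[cbind(st[!amb], which(!amb))] <- 1
    if (any(amb)) M[, amb] <- 1
    partial[[tip]] <- M
  }
  msgs <- if (keep_messages) vector("list", nrow(tp$edge)) else NULL
  scale_log <- numeric(npat)
  for (e in seq_len(nrow(tp$edge))) {
    parent <- tp$edge[e, 1]; child <- tp$edge[e, 2]
    msg <- Plist[[e]] %*% partial[[child]]
    if (keep_messages) msgs[[e]] <- msg
    if (is.null(partial[[parent]])) partial[[parent]] <- msg
    else partial[[parent]] <- partial[[parent]] * msg
    # underflow guard: only worth checking on deep trees, where partial
    # products can leave double range
    if (nrow(tp$edge) > 60) {
      mx <- apply(partial[[parent]], 2, max)
      low <- mx < 1e-200 & mx > 0
      if (any(low)) {
        partial[[parent]][, low] <-
          partial[[parent]][, low, drop = FALSE] /
          rep(mx[low], each = n_state)
        scale_log[low] <- scale_log[low] + log(mx[low])
      }
    }
  }
  list(partial = partial, scale_log = scale_log, msgs = msgs)
}

# Log-likelihood for one homogeneous block of patterns under (pi, eigen).
block_loglik <- function(tp, eg, pat, w) {
  Plist <- lapply(tp$len, function(t) prob_matrix(eg, t))
  pr <- prune_pass(tp, Plist, pat, length(eg$pi))
  site <- as.numeric(eg$pi %*% pr$partial[[tp$root]])
  if (any(site <= 0)) return(-Inf)
  sum(w * (log(site) + pr$scale_log))
}

# Per-pattern site likelihoods (not logged; scale returned separately).
block_site_lik <- function(tp, eg, pat) {
  Plist <- lapply(tp$len, function(t) prob_matrix(eg, t))
  pr <- prune_pass(tp, Plist, pat, length(eg$pi))
  list(lik = as.numeric(eg$pi %*% pr$partial[[tp$root]]),
       scale_log = pr$scale_log)
}

#' Phylogenetic log-likelihood of a codon alignment under a GY94 model
#'
#' Felsenstein pruning over the sense-codon state space, with transition
#' probabilities from the spectral decomposition of the (reversible) rate
#' matrix. Each alignment column evolves under the omega assigned to it,
#' allowing fixed-sites partition models; gapped or masked codons at the
#' tips are fully ambiguous states.
#'
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   nucleotide substitutions per codon; tips must match the alignment taxa.
#' @param aln A `codon_alignment`.
#' @param pi Sense-codon frequencies (default: F3x4 from `aln`).
#' @param kappa Transition/transversion ratio.
#' @param omega Scalar omega, or a vector of length `aln$n_col` assigning an
#'   omega to every column.
#' @return Scalar log-likelihood.
#' @export
tree_loglik <- function(tree, aln, pi = NULL, kappa = 2, omega = 0.2) {
  gc <- genetic_code(aln$code)
  stops_present <- aln$codons %in% gc$stops
  if (any(stops_present)) {
    bad <- which(matrix(stops_present, nrow(aln$codons)), arr.ind = TRUE)[1, ]
    stop("stop codon at taxon ", aln$taxa[bad[1]], ", column ", bad[2])
  }
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  tp <- prepare_tree(tree, aln$taxa)
  states <- encode_states(aln, gc)[tp$tip_index, , drop = FALSE]
  if (length(omega) == 1L) omega <- rep(omega, aln$n_col)
  stopifnot(length(omega) == aln$n_col)
  total <- 0
  for (om in unique(omega)) {
    cols <- which(omega == om)
    pc <- pattern_compress(states[, cols, drop = FALSE])
    eg <- codon_eigen(pi, kappa, om, aln$code)
    total <- total + block_loglik(tp, eg, pc$pat, pc$w)
  }
  total
}
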