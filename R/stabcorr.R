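# Stability statistics: class-wise delta-delta-G summaries, pairwise Welch
# contrasts, and the Sigma-dN vs mean delta-delta-G correlation.

#' Read a per-residue stability table (TSV: chain, resno, ddg_kj_mol)
#' @param path TSV path with a header.
#' @return A `ddg_table` data frame.
#' @export
read_ddg_tsv <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("chain", "resno", "ddg_kj_mol")
  if (!all(need %in% names(out)))
    stop("ddg table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(out$ddg_kj_mol))) stop("non-finite delta-delta-G values")
  class(out) <- c("ddg_table", "data.frame")
  out
}

#' Class-wise stability statistics and pairwise contrasts
#'
#' Joins a per-residue stability-change table onto structural labels and
#' summarises delta-delta-G per (subunit x class): n, mean, standard error
#' and standard deviation. All pairwise class contrasts within each subunit
#' (and across subunits pooled) are tested with Welch's unequal-variance
#' two-sided t-test, with significance tiers at 0.05 and 0.0005.
#'
#' @param ddg A `ddg_table` (chain, resno, ddg_kj_mol).
#' @param labels A `site_labels` data frame.
#' @param min_n Minimum group size to report (smaller groups are dropped
#'   with a warning).
#' @return List with `stats` (data frame: subunit, class, n, mean, se, sd)
#'   and `contrasts` (data frame: subunit, class_a, class_b, t, df, p,
#'   tier, degenerate).
#' @export
group_ddg_stats <- function(ddg, labels, min_n = 2) {
  lab <- labels[, c("chain", "resno", "site_class")]
  m <- merge(ddg, lab, by = c("chain", "resno"))
  if (nrow(m) == 0L) stop("stability table and labels share no residues")
  m_all <- m; m_all$chain <- "ALL"
  m2 <- rbind(m, m_all)
  grp <- split(m2$ddg_kj_mol, list(m2$chain, m2$site_class), drop = TRUE)
  keep <- vapply(grp, length, integer(1)) >= min_n
  if (any(!keep))
    warning("dropping groups with fewer than ", min_n, " residues: ",
            paste(names(grp)[!keep], collapse = ", "))
  grp <- grp[keep]
  nm <- do.call(rbind, strsplit(names(grp), ".", fixed = TRUE))
  stats <- data.frame(
    subunit = nm[, 1], class = nm[, 2],
    n = vapply(grp, length, integer(1)),
    mean = vapply(grp, mean, numeric(1)),
    se = vapply(grp, function(v) sd(v) / sqrt(length(v)), numeric(1)),
    sd = vapply(grp, sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  contrasts <- list()
  for (su in unique(stats$subunit)) {
    cls <- stats$class[stats$subunit == su]
    if (length(cls) < 2) next
    for (i in seq_len(length(cls) - 1)) {
      for (j in (i + 1):length(cls)) {
        va <- grp[[paste(su, cls[i], sep = ".")]]
        vb <- grp[[paste(su, cls[j], sep = ".")]]
        degen <- sd(va) == 0 && sd(vb) == 0
        if (degen) {
          tt <- list(statistic = NA_real_, parameter = NA_real_,
                     p.value = if (mean(va) == mean(vb)) 1 else 0)
        } else {
          tt <- t.test(va, vb, var.equal = FALSE)
        }
        p <- tt$p.value
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          subunit = su, class_a = cls[i], class_b = cls[j],
          t = unname(tt$statistic), df = unname(tt$parameter), p = p,
          tier = if (is.na(p)) "" else if (p < 0.0005) "**"
                 else if (p < 0.05) "*" else "",
          degenerate = degen, stringsAsFactors = FALSE)
      }
    }
  }
  list(stats = stats,
       contrasts = if (length(contrasts)) do.call(rbind, contrasts) else
         data.frame())
}

#' Correlation between Sigma-dN and mean stability change across classes
#'
#' Pearson correlation (two-sided p from the t distribution with n - 2 df)
#' between per-class Sigma-dN values and per-class mean delta-delta-G. A
#' negative correlation indicates that more destabilising residue classes
#' are more evolutionarily constrained. Supports leave-one-out re-runs to
#' probe the influence of a labelled point.
#'
#' @param points Data frame with columns `sum_dn`, `mean_ddg` and
#'   optionally `label`.
#' @param exclude Optional label (or row index) to drop before computing.
#' @return A `correlation_result`: list with `n`, `r`, `p`, `points`,
#'   `excluded`.
#' @export
dn_ddg_correlation <- function(points, exclude = NULL) {
  stopifnot(all(c("sum_dn", "mean_ddg") %in% names(points)))
  excluded <- NULL
  if (!is.null(exclude)) {
    idx <- if (is.character(exclude)) which(points$label %in% exclude) else
      as.integer(exclude)
    if (length(idx)) {
      excluded <- points[idx, , drop = FALSE]
      points <- points[-idx, , drop = FALSE]
    }
  }
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  if (sd(points$sum_dn) == 0 || sd(points$mean_ddg) == 0)
    return(structure(list(n = n, r = NA_real_, p = NA_real_,
                          points = points, excluded = excluded),
                     class = "correlation_result"))
  ct <- cor.test(points$sum_dn, points$mean_ddg, method = "pearson")
  structure(list(n = n, r = unname(ct$estimate), p = ct$p.value,
                 points = points, excluded = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: n = %d, Pearson r = %.3f, p = %.4f\n",
              x$n, x$r, x$p))
  invisible(x)
}
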