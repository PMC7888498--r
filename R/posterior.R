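#' Derive genetic parameters for every stored draw
#'
#' For each stored (G, R) draw, computes per trait the additive,
#' residual and phenotypic variances and the heritability
#' `h2 = sigma2_a / sigma2_p`, and for each trait pair the genetic
#' correlation `r_g = g_ij / sqrt(g_ii g_jj)` and phenotypic
#' correlation `r_p = (g_ij + r_ij) / sqrt(sigma2_p_i sigma2_p_j)`.
#' Derivation happens draw by draw, before any averaging, so the
#' reported posterior mean of each ratio is the mean of the ratio.
#'
#' @param store An `ltm_store` from a fit with an additive genetic
#'   effect, or an `ltm_fit`.
#' @return A data frame with one row per stored draw.
#' @export
derive_samples <- function(store) {
  if (inherits(store, "ltm_fit")) store <- store$store
  stopifnot(inherits(store, "ltm_store"))
  if (is.null(store$G))
    stop("store has no additive covariance draws (fit without pedigree)")
  traits <- store$traits
  nt <- length(traits)
  ns <- length(store$cycle)
  if (ns < 1L) stop("empty sample store")
  out <- data.frame(cycle = store$cycle)
  ga <- store$G; re <- store$R
  idx <- function(i, j) (j - 1L) * nt + i
  gm <- t(apply(ga, 3L, identity)); rm_ <- t(apply(re, 3L, identity))
  if (ns == 1L) { gm <- matrix(gm, 1L); rm_ <- matrix(rm_, 1L) }
  sp <- matrix(NA_real_, ns, nt)
  for (t in seq_len(nt)) {
    sa <- gm[, idx(t, t)]; se <- rm_[, idx(t, t)]
    if (any(sa < 0) || any(se <= 0)) stop("corrupt stored draw: negative variance")
    sp[, t] <- sa + se
    out[[paste0("sigma2_a_", traits[t])]] <- sa
    out[[paste0("sigma2_e_", traits[t])]] <- se
    out[[paste0("sigma2_p_", traits[t])]] <- sp[, t]
    out[[paste0("h2_", traits[t])]] <- sa / sp[, t]
  }
  for (i in seq_len(nt)) for (j in seq_len(nt)) if (i < j) {
    gij <- gm[, idx(i, j)]
    out[[paste0("rg_", traits[i], "_", traits[j])]] <-
      gij / sqrt(gm[, idx(i, i)] * gm[, idx(j, j)])
    out[[paste0("rp_", traits[i], "_", traits[j])]] <-
      (gij + rm_[, idx(i, j)]) / sqrt(sp[, i] * sp[, j])
  }
  out
}

#' Posterior means and standard deviations of derived parameters
#'
#' @param derived Data frame from [derive_samples()] (the `cycle`
#'   column is ignored), or an `ltm_store`/`ltm_fit` to derive first.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_samples <- function(derived) {
  if (!is.data.frame(derived)) derived <- derive_samples(derived)
  derived$cycle <- NULL
  if (nrow(derived) < 2L) stop("need at least 2 samples to summarize")
  data.frame(parameter = names(derived),
             mean = vapply(derived, mean, 0),
             sd = vapply(derived, stats::sd, 0),
             n = nrow(derived), row.names = NULL)
}

#' Summarize a linear-threshold model fit
#'
#' @param object An `ltm_fit`.
#' @param ... Unused.
#' @return A `summary.ltm_fit` object: the parameter table plus
#'   heritability / genetic-correlation / phenotypic-correlation
#'   matrices of posterior means and SDs.
#' @export
summary.ltm_fit <- function(object, ...) {
  s <- summarize_samples(derive_samples(object$store))
  summary_from_table(s, object$store$traits)
}

#' @export
print.summary.ltm_fit <- function(x, ...) {
  cat("Posterior summaries over", x$n_samples, "stored draws\n\n")
  writeLines(format_report(x, "components"))
  cat("\n")
  writeLines(format_report(x, "correlation_matrix"))
  invisible(x)
}

fmt_cell <- function(mean, sd, digits = 2) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean, sd)
}

#' Render a posterior summary as a text table
#'
#' Two styles are offered, mirroring the conventional report layouts
#' for this model family: `"components"` lists per-trait variance
#' components and heritability as "mean (SD)"; `"correlation_matrix"`
#' places heritabilities on the diagonal, genetic correlations above
#' it and phenotypic correlations below it. Values are rounded to two
#' decimals; full precision is available from [summarize_samples()]
#' and [write_summary()].
#'
#' @param x A `summary.ltm_fit` (or an `ltm_fit`, summarized first).
#' @param style `"components"` or `"correlation_matrix"`.
#' @param digits Decimal places (default 2).
#' @return Character vector of report lines.
#' @export
format_report <- function(x, style = c("components", "correlation_matrix"),
                          digits = 2) {
  if (inherits(x, "ltm_fit")) x <- summary(x)
  stopifnot(inherits(x, "summary.ltm_fit"))
  style <- match.arg(style)
  traits <- x$traits
  nt <- length(traits)
  wid <- max(nchar(traits), 6L)
  if (style == "components") {
    comp <- x$components
    header <- sprintf("%-*s  %-14s  %-14s  %-14s  %-14s", wid, "Trait",
                      "sigma2_a", "sigma2_e", "sigma2_p", "h2")
    rows <- vapply(seq_len(nt), function(k) {
      sprintf("%-*s  %-14s  %-14s  %-14s  %-14s", wid, comp$trait[k],
              fmt_cell(comp$sigma2_a[k], comp$sigma2_a_sd[k], digits),
              fmt_cell(comp$sigma2_e[k], comp$sigma2_e_sd[k], digits),
              fmt_cell(comp$sigma2_p[k], comp$sigma2_p_sd[k], digits),
              fmt_cell(comp$h2[k], comp$h2_sd[k], digits))
    }, "")
    c(header, rows)
  } else {
    # diagonal h2, genetic above, phenotypic below
    cellw <- 14L
    header <- paste0(formatC("", width = wid), "  ",
                     paste(formatC(traits, width = cellw), collapse = "  "))
    rows <- vapply(seq_len(nt), function(i) {
      cells <- vapply(seq_len(nt), function(j) {
        cell <- if (i == j) fmt_cell(x$h2[i], x$h2_sd[i], digits)
        else if (i < j) fmt_cell(x$rg[i, j], x$rg_sd[i, j], digits)
        else fmt_cell(x$rp[i, j], x$rp_sd[i, j], digits)
        formatC(cell, width = cellw)
      }, "")
      paste0(formatC(traits[i], width = wid, flag = "-"), "  ",
             paste(cells, collapse = "  "))
    }, "")
    c(header, rows)
  }
}

#' Write the machine-readable posterior summary sidecar
#' @param x A `summary.ltm_fit` or `ltm_fit`.
#' @param path Output path (tab-delimited, full precision).
#' @export
write_summary <- function(x, path) {
  if (inherits(x, "ltm_fit")) x <- summary(x)
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
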