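#' Default additive and residual covariance matrices for simulation
#'
#' Four-trait covariance matrices (NBA1, NBA2, NBA3, STAY14 liability)
#' on the scale typical of tropical maternal-line sow populations:
#' litter-size phenotypic variances near 6.2-6.9 with low heritability,
#' liability residual variance pinned to 1, strong genetic correlations
#' among parities and moderate favourable genetic correlations between
#' first-parity litter size and stayability.
#'
#' @name sim_covariances
#' @keywords internal
NULL

default_true_G <- function() {
  sa <- c(0.04, 0.25, 0.27, 0.05)
  rg <- matrix(c(1, 0.73, 0.89, 0.65,
                 0.73, 1, 0.85, 0.59,
                 0.89, 0.85, 1, 0.43,
                 0.65, 0.59, 0.43, 1), 4, 4)
  G <- rg * sqrt(outer(sa, sa))
  dimnames(G) <- list(ltm_trait_names(), ltm_trait_names())
  G
}

default_true_R <- function() {
  se <- c(6.84, 6.11, 5.91, 1.00)
  sp <- c(0.04, 0.25, 0.27, 0.05) + se
  rp <- matrix(c(1, 0.12, 0.11, 0.08,
                 0.12, 1, 0.15, 0.09,
                 0.11, 0.15, 1, 0.12,
                 0.08, 0.09, 0.12, 1), 4, 4)
  G <- default_true_G()
  R <- rp * sqrt(outer(sp, sp)) - G
  diag(R) <- se
  dimnames(R) <- dimnames(G)
  R
}

ltm_trait_names <- function() c("nba1", "nba2", "nba3", "stay14")

is_pd <- function(m) {
  ev <- eigen(0.5 * (m + t(m)), symmetric = TRUE, only.values = TRUE)$values
  all(ev > 1e-10)
}

#' Configuration for the synthetic herd generator
#'
#' The defaults describe a purebred maternal-line nucleus herd:
#' founder sires and dams mated at random over discrete generations,
#' age at first farrowing 367 +/- 26 d truncated to [280, 460], litter
#' sizes rising from about 9.4 to 10.5 across parities 1-3 with
#' phenotypic SD near 2.6, a stayability liability giving roughly 76%
#' of sows a fourth farrowing, liability-linked culling of the
#' remainder across parities 1-3, and right-censoring of a fraction of
#' sows still in the herd when data collection ends.
#'
#' @param n_founder_sires,n_founder_dams Founder counts.
#' @param daughters_per_dam Recorded daughters per mating.
#' @param n_generations Discrete generations of matings (0 = founders
#'   only).
#' @param true_G,true_R True 4x4 additive and residual covariance
#'   matrices; `true_R[4,4]` must be 1.
#' @param intercepts Trait means on the observed/liability scale.
#' @param aff_mean,aff_sd,aff_min,aff_max Age-at-first-farrowing
#'   distribution (days; truncated normal).
#' @param aff_slope Per-trait regression on centered AFF.
#' @param cg_effect_sd Per-trait SD of contemporary-group effects.
#' @param n_herds,start_year,n_years Structure generating the
#'   herd-year-season contemporary groups.
#' @param culling `"liability"` (default: lower stayability liability
#'   culled earlier) or `"random"`.
#' @param removal_probs Probabilities of removal at parities 1-3 for a
#'   culled sow (sums to 1).
#' @param censor_frac Fraction of sows right-censored (no removal date,
#'   under four parities, stayability unobserved).
#' @param round_nba Round litter sizes to non-negative integers.
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founder_sires = 150L, n_founder_dams = 1000L,
                       daughters_per_dam = 3L, n_generations = 1L,
                       true_G = default_true_G(), true_R = default_true_R(),
                       intercepts = c(9.4, 10.0, 10.5, 0.72),
                       aff_mean = 367, aff_sd = 26,
                       aff_min = 280, aff_max = 460,
                       aff_slope = c(-0.005, 0, 0, -0.005),
                       cg_effect_sd = c(0.5, 0.5, 0.5, 0.2),
                       n_herds = 3L, start_year = 2008L, n_years = 4L,
                       culling = c("liability", "random"),
                       removal_probs = c(0.45, 0.30, 0.25),
                       censor_frac = 0.25, round_nba = FALSE,
                       seed = NULL) {
  culling <- match.arg(culling)
  true_G <- as.matrix(true_G); true_R <- as.matrix(true_R)
  stopifnot(nrow(true_G) == 4L, nrow(true_R) == 4L,
            length(intercepts) == 4L, length(aff_slope) == 4L,
            length(cg_effect_sd) == 4L, length(removal_probs) == 3L)
  if (abs(true_R[4, 4] - 1) > 1e-12)
    stop("true_R[4,4] (stayability liability residual variance) must be 1")
  if (!is_pd(true_R)) stop("true_R is not positive definite")
  if (!all(diag(true_G) == 0) && !is_pd(true_G))
    stop("true_G is not positive definite")
  if (abs(sum(removal_probs) - 1) > 1e-8 || any(removal_probs < 0))
    stop("removal_probs must be non-negative and sum to 1")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must be in [0,1)")
  structure(list(
    n_founder_sires = as.integer(n_founder_sires),
    n_founder_dams = as.integer(n_founder_dams),
    daughters_per_dam = as.integer(daughters_per_dam),
    n_generations = as.integer(n_generations),
    true_G = true_G, true_R = true_R, intercepts = intercepts,
    aff_mean = aff_mean, aff_sd = aff_sd, aff_min = aff_min,
    aff_max = aff_max, aff_slope = aff_slope,
    cg_effect_sd = cg_effect_sd, n_herds = as.integer(n_herds),
    start_year = as.integer(start_year), n_years = as.integer(n_years),
    culling = culling, removal_probs = removal_probs,
    censor_frac = censor_frac, round_nba = isTRUE(round_nba),
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders are unrelated; in each generation every current dam is
#' mated to a sire drawn at random, producing `daughters_per_dam`
#' recorded daughters (and one unrecorded son, used as a sire candidate
#' when more generations follow).
#'
#' @param config A [sim_config()].
#' @return Data frame `animal,sire,dam,sex,generation,recorded`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_founder_sires; nd <- config$n_founder_dams
  ped <- data.frame(
    animal = c(sprintf("S0_%04d", seq_len(ns)), sprintf("D0_%04d", seq_len(nd))),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), c(ns, nd)),
    generation = 0L,
    recorded = FALSE, stringsAsFactors = FALSE)
  sires <- ped$animal[ped$sex == "M"]
  dams <- ped$animal[ped$sex == "F"]
  for (g in seq_len(config$n_generations)) {
    mate <- sample(sires, length(dams), replace = TRUE)
    kd <- config$daughters_per_dam
    daughters <- data.frame(
      animal = sprintf("F%d_%05d", g, seq_len(length(dams) * kd)),
      sire = rep(mate, each = kd), dam = rep(dams, each = kd),
      sex = "F", generation = g, recorded = TRUE,
      stringsAsFactors = FALSE)
    gen_new <- daughters
    if (g < config$n_generations) {
      sons <- data.frame(
        animal = sprintf("M%d_%05d", g, seq_along(dams)),
        sire = mate, dam = dams, sex = "M", generation = g,
        recorded = FALSE, stringsAsFactors = FALSE)
      gen_new <- rbind(daughters, sons)
      sires <- sample(sons$animal, min(ns, nrow(sons)))
      dams <- sample(daughters$animal, min(nd, nrow(daughters)))
    }
    ped <- rbind(ped, gen_new)
  }
  ped
}

#' Gene-drop multivariate breeding values down a pedigree
#'
#' Founders are drawn from N(0, G); descendants receive the parental
#' average plus a Mendelian-sampling deviation with covariance
#' `d_i * G`, where `d_i = 1 - 0.25 (1 + F_s) - 0.25 (1 + F_d)` and an
#' unknown parent's term is dropped (its gamete then carries founder
#' variance).
#'
#' @param ped A `renum_ped` (or raw pedigree data frame).
#' @param true_G Additive covariance matrix (any dimension).
#' @return Matrix of breeding values, one row per pedigree code,
#'   rownames = original ids.
#' @export
drop_breeding_values <- function(ped, true_G) {
  if (!inherits(ped, "renum_ped")) ped <- ped_renumber(ped)
  nt <- nrow(true_G)
  if (all(true_G == 0)) {
    a <- matrix(0, ped$n, nt)
    rownames(a) <- ped$id
    return(a)
  }
  if (!is_pd(true_G)) stop("true_G is not positive definite")
  L <- t(chol(true_G))
  Fv <- ped_inbreeding(ped)
  n <- ped$n
  a <- matrix(0, n, nt)
  z <- matrix(stats::rnorm(n * nt), n, nt) %*% t(L)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    di <- 1 - (if (s > 0L) 0.25 * (1 + Fv[s]) else 0) -
              (if (d > 0L) 0.25 * (1 + Fv[d]) else 0)
    pa <- 0.5 * ((if (s > 0L) a[s, ] else 0) + (if (d > 0L) a[d, ] else 0))
    a[i, ] <- pa + sqrt(di) * z[i, ]
  }
  rownames(a) <- ped$id
  a
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd); pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Simulate phenotype records for a pedigreed herd
#'
#' Draws AFF from a truncated normal, assigns herds and calendar dates
#' (hence herd-year-season contemporary groups with their own random
#' effects), and generates the four trait values as
#' intercept + CG effect + AFF slope x (AFF - mean) + breeding value +
#' residual, with residuals drawn from `true_R`. Stayability is 1
#' exactly when its liability exceeds 0. Farrowing dates are spaced
#' 140-165 days apart so the calendar is self-consistent.
#'
#' @param ped Pedigree data frame from [simulate_pedigree()].
#' @param bv Breeding-value matrix from [drop_breeding_values()].
#' @param config A [sim_config()].
#' @return A `sim_herd` object (no culling applied yet; see
#'   [apply_sequential_missingness()]).
#' @export
simulate_records <- function(ped, bv, config) {
  stopifnot(inherits(config, "sim_config"))
  sows <- ped$animal[ped$recorded]
  n <- length(sows)
  if (n == 0L) stop("pedigree has no recorded sows")
  aff <- round(rtrunc_norm(n, config$aff_mean, config$aff_sd,
                           config$aff_min, config$aff_max))
  birth <- as.Date(sprintf(
    "%d-01-01", sample(config$start_year + seq_len(config$n_years) - 1L,
                       n, replace = TRUE))) +
    sample.int(365L, n, replace = TRUE) - 1L
  first_farrow <- birth + aff
  herd <- sprintf("H%d", sample.int(config$n_herds, n, replace = TRUE))
  cg <- make_cg(herd, first_farrow)
  cg_lev <- unique(cg)
  cg_eff <- matrix(stats::rnorm(length(cg_lev) * 4L), length(cg_lev), 4L) %*%
    diag(config$cg_effect_sd)
  rownames(cg_eff) <- cg_lev
  e <- matrix(stats::rnorm(n * 4L), n, 4L) %*% chol(config$true_R)
  av <- bv[sows, , drop = FALSE]
  lin <- matrix(config$intercepts, n, 4L, byrow = TRUE) +
    cg_eff[cg, , drop = FALSE] +
    outer(aff - config$aff_mean, config$aff_slope)
  yy <- lin + av + e
  stay_true <- as.integer(yy[, 4L] > 0)
  nba <- yy[, 1:3, drop = FALSE]
  nba4 <- lin[, 3L] + av[, 3L] + stats::rnorm(n, 0, sqrt(config$true_R[3, 3]))
  if (config$round_nba) {
    nba <- pmax(round(nba), 0)
    nba4 <- pmax(round(nba4), 0)
  }
  # farrowing intervals 140-165 d keep parities calendar-consistent
  gaps <- matrix(sample(140:165, n * 3L, replace = TRUE), n, 3L)
  fdates <- cbind(first_farrow,
                  first_farrow + gaps[, 1L],
                  first_farrow + rowSums(gaps[, 1:2]),
                  first_farrow + rowSums(gaps))
  structure(list(
    pedigree = ped[c("animal", "sire", "dam")],
    sows = data.frame(sow = sows, herd = herd, birth_date = birth,
                      aff = aff, cg = cg, stringsAsFactors = FALSE),
    nba = cbind(nba, nba4 = nba4), farrow_dates = fdates,
    liability = yy[, 4L], stay_true = stay_true,
    n_parities = ifelse(stay_true == 1L, 4L, NA_integer_),
    removal_parity = rep(NA_integer_, n),
    censored = rep(FALSE, n),
    bv = bv, cg_eff = cg_eff, config = config),
    class = "sim_herd")
}

#' Apply culling-driven sequential missingness
#'
#' Sows whose stayability liability fell below the threshold are
#' assigned a removal parity in 1-3 — by liability rank under
#' `culling = "liability"` (lower liability culled earlier, the
#' selection mechanism a joint threshold-linear analysis is designed
#' for) or multinomially under `"random"` — and their later farrowings
#' are deleted. A `censor_frac` fraction of sows is right-censored:
#' the removal date is withheld and the farrowing history truncated,
#' leaving stayability unobserved.
#'
#' @param herd A `sim_herd` from [simulate_records()].
#' @param config A [sim_config()] (defaults to the herd's own).
#' @return The herd with `n_parities`, `removal_parity` and `censored`
#'   filled in.
#' @export
apply_sequential_missingness <- function(herd, config = herd$config) {
  stopifnot(inherits(herd, "sim_herd"))
  n <- length(herd$stay_true)
  culled <- which(herd$stay_true == 0L)
  rp <- rep(NA_integer_, n)
  if (length(culled)) {
    if (config$culling == "liability") {
      # lower liability -> earlier removal
      qcut <- cumsum(config$removal_probs)
      rnk <- rank(herd$liability[culled], ties.method = "random") /
        length(culled)
      rp[culled] <- findInterval(rnk, qcut, left.open = TRUE) + 1L
    } else {
      rp[culled] <- sample(1:3, length(culled), replace = TRUE,
                           prob = config$removal_probs)
    }
  }
  npar <- ifelse(herd$stay_true == 1L, 4L, rp)
  cens <- rep(FALSE, n)
  if (config$censor_frac > 0) {
    cens <- stats::runif(n) < config$censor_frac
    k <- sample(1:3, n, replace = TRUE)
    npar[cens] <- pmin(npar[cens], k[cens])
  }
  herd$removal_parity <- rp
  herd$n_parities <- npar
  herd$censored <- cens
  herd
}

#' Generate a complete synthetic herd
#'
#' Convenience wrapper: pedigree, breeding values, records, culling.
#' @param config A [sim_config()].
#' @return A `sim_herd`.
#' @export
simulate_herd <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ped <- simulate_pedigree(config)
  bv <- drop_breeding_values(ped[c("animal", "sire", "dam")], config$true_G)
  herd <- simulate_records(ped, bv, config)
  apply_sequential_missingness(herd, config)
}

#' @export
print.sim_herd <- function(x, ...) {
  cat(sprintf("Synthetic herd: %d pedigree animals, %d recorded sows\n",
              nrow(x$pedigree), length(x$stay_true)))
  cat(sprintf("  stayability (true): %.3f   censored: %.3f\n",
              mean(x$stay_true), mean(x$censored)))
  invisible(x)
}

#' The herd's own analysis table (generator bookkeeping)
#'
#' Builds the analysis table directly from the simulation truth, for
#' round-trip comparison against the editing pipeline run on the
#' written record files.
#'
#' @param herd A `sim_herd` after [apply_sequential_missingness()].
#' @return Data frame `sow,cg,aff,nba1,nba2,nba3,stay14`.
#' @export
herd_analysis_table <- function(herd) {
  stopifnot(inherits(herd, "sim_herd"))
  np <- herd$n_parities
  nba <- herd$nba[, 1:3, drop = FALSE]
  for (p in 1:3) nba[np < p, p] <- NA_real_
  stay <- ifelse(herd$censored & np < 4L, NA_integer_, herd$stay_true)
  out <- data.frame(sow = herd$sows$sow, cg = herd$sows$cg,
                    aff = herd$sows$aff,
                    nba1 = nba[, 1L], nba2 = nba[, 2L], nba3 = nba[, 3L],
                    stay14 = stay, stringsAsFactors = FALSE)
  out[order(out$sow), , drop = FALSE]
}

#' Write a synthetic herd to the package's file dialects
#'
#' Emits `pedigree.csv` (animal,sire,dam; unknown = 0), `records.csv`
#' (the long sow-record format consumed by [read_sow_records()]) and a
#' plain-text truth sidecar (`truth_G.csv`, `truth_R.csv`,
#' `breeding_values.csv`) for recovery scoring.
#'
#' @param herd A `sim_herd`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_herd <- function(herd, dir) {
  stopifnot(inherits(herd, "sim_herd"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- herd$pedigree
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  utils::write.csv(ped, file.path(dir, "pedigree.csv"),
                   row.names = FALSE, quote = FALSE)
  n <- length(herd$stay_true)
  np <- herd$n_parities
  fdate <- function(x) format(as.Date(x, origin = "1970-01-01"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- np[i]
    rem <- if (!herd$censored[i] && herd$stay_true[i] == 0L)
      fdate(herd$farrow_dates[i, k] + 45L) else ""
    rows[[i]] <- data.frame(
      sow = herd$sows$sow[i], herd = herd$sows$herd[i],
      birth_date = format(herd$sows$birth_date[i]),
      parity = seq_len(k),
      farrow_date = fdate(herd$farrow_dates[i, seq_len(k)]),
      nba = herd$nba[i, seq_len(k)],
      removal_date = rem, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(herd$config$true_G),
                   file.path(dir, "truth_G.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(herd$config$true_R),
                   file.path(dir, "truth_R.csv"), row.names = FALSE)
  bv <- data.frame(animal = rownames(herd$bv), herd$bv,
                   stringsAsFactors = FALSE)
  names(bv)[-1] <- paste0("bv_", ltm_trait_names())
  utils::write.csv(bv, file.path(dir, "breeding_values.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
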