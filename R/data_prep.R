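#' Age at first farrowing in whole days
#' @param birth_date,first_farrowing_date `Date` vectors (recycled).
#' @return Integer day differences.
#' @export
compute_aff <- function(birth_date, first_farrowing_date) {
  b <- as.Date(birth_date); f <- as.Date(first_farrowing_date)
  d <- as.integer(f - b)
  if (any(d < 0, na.rm = TRUE))
    stop("first farrowing precedes birth for ", sum(d < 0, na.rm = TRUE),
         " record(s)")
  d
}

#' Season of a calendar month
#'
#' Tropical production seasons: summer (March-June), rainy
#' (July-October) and winter (November-February).
#'
#' @param month Integer month(s) in 1..12.
#' @return Character vector of season labels.
#' @export
assign_season <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month) | month < 1L | month > 12L))
    stop("month must be in 1..12")
  c("winter", "winter", "summer", "summer", "summer", "summer",
    "rainy", "rainy", "rainy", "rainy", "winter", "winter")[month]
}

#' Contemporary-group label: herd x year x season of first farrowing
#' @param herd Herd identifier(s).
#' @param first_farrow_date First-farrowing `Date`(s).
#' @return Character labels like `"H1-2010-summer"`.
#' @export
make_cg <- function(herd, first_farrow_date) {
  d <- as.Date(first_farrow_date)
  paste(herd, format(d, "%Y"), assign_season(as.integer(format(d, "%m"))),
        sep = "-")
}

#' Read sow reproduction records (long format)
#'
#' One row per farrowing:
#' `sow,herd,birth_date,parity,farrow_date,nba,removal_date` with
#' ISO-8601 dates; `removal_date` blank for sows still in the herd.
#'
#' @param path CSV path.
#' @return Data frame with parsed dates.
#' @export
read_sow_records <- function(path) {
  if (!file.exists(path)) stop("sow record file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("sow", "herd", "birth_date", "parity", "farrow_date", "nba")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sow record file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("sow record file is empty: ", path)
  if (!"removal_date" %in% names(df)) df$removal_date <- ""
  blank <- function(x) ifelse(x == "" | is.na(x), NA_character_, x)
  data.frame(sow = df$sow, herd = df$herd,
             birth_date = as.Date(blank(df$birth_date)),
             parity = suppressWarnings(as.integer(blank(df$parity))),
             farrow_date = as.Date(blank(df$farrow_date)),
             nba = suppressWarnings(as.numeric(blank(df$nba))),
             removal_date = as.Date(blank(df$removal_date)),
             stringsAsFactors = FALSE)
}

#' Stayability coding from first to fourth parity
#'
#' A sow farrowing a fourth parity is coded 1; a sow with a removal
#' date and no fourth parity is coded 0; a sow still present at the end
#' of data collection without a fourth-parity opportunity is
#' right-censored and coded `NA` (excluded from the binary-trait
#' likelihood rather than treated as culled).
#'
#' @param parities Integer vector of recorded parities for one sow.
#' @param removal_date The sow's removal `Date`, or `NA`.
#' @param data_end_date End of data collection (unused beyond the
#'   censoring convention; kept for explicitness).
#' @return 0, 1 or `NA`.
#' @export
code_stay14 <- function(parities, removal_date, data_end_date = NULL) {
  if (any(parities >= 4L)) return(1L)
  if (!is.na(removal_date)) return(0L)
  NA_integer_
}

#' Apply editing rules and build the analysis table
#'
#' Implements the record edits and trait definitions for the joint
#' litter-size / stayability analysis: sows with a missing birth date,
#' any farrowing missing its date or parity, or an age at first
#' farrowing (AFF) strictly below 280 d or strictly above 460 d are
#' dropped (the boundaries 280 and 460 are retained). Retained sows get
#' a herd-year-season contemporary group from their first farrowing,
#' the AFF covariate, litter sizes NBA1-NBA3 (missing after culling)
#' and the STAY14 code.
#'
#' @param records Long-format data frame from [read_sow_records()].
#' @param aff_min,aff_max AFF retention bounds in days (inclusive).
#' @param data_end_date End of data collection; defaults to the latest
#'   farrowing date present.
#' @return A list with `data` (one row per retained sow:
#'   `sow,cg,aff,nba1,nba2,nba3,stay14`) and `log` (per-rule drop
#'   counts plus per-sow reason codes).
#' @export
edit_records <- function(records, aff_min = 280L, aff_max = 460L,
                         data_end_date = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(data_end_date))
    data_end_date <- max(records$farrow_date, na.rm = TRUE)
  sows <- split(records, records$sow)
  reasons <- character(0)
  rows <- vector("list", length(sows))
  gap_warned <- 0L
  for (k in seq_along(sows)) {
    r <- sows[[k]]
    sow <- r$sow[1]
    if (anyNA(r$birth_date)) { reasons[sow] <- "missing_birth_date"; next }
    if (anyNA(r$farrow_date)) { reasons[sow] <- "missing_farrow_date"; next }
    if (anyNA(r$parity)) { reasons[sow] <- "missing_parity"; next }
    r <- r[order(r$parity), ]
    if (anyDuplicated(r$parity)) { reasons[sow] <- "duplicate_parity"; next }
    if (!1L %in% r$parity) { reasons[sow] <- "no_first_parity"; next }
    first <- r$farrow_date[r$parity == 1L]
    aff <- compute_aff(r$birth_date[1], first)
    if (aff < aff_min || aff > aff_max) { reasons[sow] <- "aff_out_of_range"; next }
    nba <- rep(NA_real_, 3L)
    for (p in 1:3) if (p %in% r$parity) nba[p] <- r$nba[r$parity == p]
    # parity gaps (e.g. 1 and 3 recorded, 2 absent) leave the gap missing
    if (any(diff(sort(r$parity)) > 1L)) gap_warned <- gap_warned + 1L
    stay <- code_stay14(r$parity, r$removal_date[1], data_end_date)
    rows[[k]] <- data.frame(
      sow = sow, cg = make_cg(r$herd[1], first), aff = aff,
      nba1 = nba[1], nba2 = nba[2], nba3 = nba[3], stay14 = stay,
      stringsAsFactors = FALSE)
  }
  if (gap_warned > 0L)
    warning(gap_warned, " sow(s) have parity gaps; gap litters left missing")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(sow = character(0), cg = character(0),
                      aff = integer(0), nba1 = numeric(0), nba2 = numeric(0),
                      nba3 = numeric(0), stay14 = integer(0))
  rownames(out) <- NULL
  log <- list(n_in = length(sows), n_out = nrow(out),
              n_dropped = length(reasons),
              drops_by_rule = if (length(reasons)) table(reasons) else table(character(0)),
              reasons = reasons)
  class(log) <- "edit_log"
  list(data = out, log = log)
}

#' @export
print.edit_log <- function(x, ...) {
  cat(sprintf("Edit log: %d sows in, %d retained, %d dropped\n",
              x$n_in, x$n_out, x$n_dropped))
  if (x$n_dropped > 0L) {
    for (rule in names(x$drops_by_rule))
      cat(sprintf("  %-22s %d\n", rule, x$drops_by_rule[[rule]]))
  }
  invisible(x)
}

#' Write / read the analysis table
#'
#' CSV with columns `sow,cg,aff,nba1,nba2,nba3,stay14`; missing values
#' written as `NA`.
#' @param data Analysis data frame from [edit_records()].
#' @param path File path.
#' @export
write_analysis_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  if (!file.exists(path)) stop("analysis table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sow = "character", cg = "character"))
}
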