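#' @keywords internal
new_ltm_store <- function(G, R, cycle, traits, binary, chain) {
  structure(list(G = G, R = R, cycle = as.integer(cycle),
                 traits = traits, binary = binary, chain = chain),
            class = "ltm_store")
}

#' @export
print.ltm_store <- function(x, ...) {
  cat(sprintf("ltm_store: %d stored (G, R) draws over traits %s\n",
              length(x$cycle), paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' Number of stored draws
#' @param x An `ltm_store`.
#' @export
length.ltm_store <- function(x) length(x$cycle)

store_hash <- function(store) {
  # cheap content hash for run manifests (no external digest dependency)
  s <- paste(store$traits, collapse = ",")
  ch <- store$chain
  key <- sprintf("%s|%d|%d|%d|%s", s, ch$n_cycles, ch$burn_in, ch$thin,
                 if (is.null(ch$seed)) "NA" else ch$seed)
  h <- 5381
  for (v in utf8ToInt(key)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

lower_tri_labels <- function(traits) {
  nt <- length(traits)
  idx <- which(lower.tri(diag(nt), diag = TRUE), arr.ind = TRUE)
  paste0(traits[idx[, "row"]], ".", traits[idx[, "col"]])
}

#' Write stored Gibbs draws to a delimited text file
#'
#' One row per stored sample: the cycle index, the free elements of G
#' (lower triangle) and the free elements of R (lower triangle, minus
#' the pinned unit variance of the binary trait). Header comment lines
#' carry the chain settings and a configuration hash.
#'
#' @param store An `ltm_store` (e.g. `fit$store`).
#' @param path Output path.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "ltm_store"))
  nt <- length(store$traits)
  low <- which(lower.tri(diag(nt), diag = TRUE))
  labs <- lower_tri_labels(store$traits)
  bidx <- if (!is.na(store$binary)) match(store$binary, store$traits) else NA
  rkeep <- seq_along(low)
  if (!is.na(bidx)) rkeep <- rkeep[low != (bidx - 1L) * nt + bidx]
  ns <- length(store$cycle)
  gm <- if (!is.null(store$G))
    t(apply(store$G, 3L, function(m) m[low])) else NULL
  rm_ <- t(apply(store$R, 3L, function(m) m[low]))[, rkeep, drop = FALSE]
  if (ns == 1L) rm_ <- matrix(rm_, nrow = 1L)
  df <- data.frame(cycle = store$cycle)
  if (!is.null(gm)) {
    gm <- if (ns == 1L) matrix(gm, nrow = 1L) else gm
    colnames(gm) <- paste0("G.", labs)
    df <- cbind(df, gm)
  }
  colnames(rm_) <- paste0("R.", labs[rkeep])
  df <- cbind(df, rm_)
  ch <- store$chain
  hdr <- c(sprintf("# stayltm sample store  hash=%s", store_hash(store)),
           sprintf("# traits=%s binary=%s", paste(store$traits, collapse = ","),
                   store$binary),
           sprintf("# n_cycles=%d burn_in=%d thin=%d seed=%s",
                   ch$n_cycles, ch$burn_in, ch$thin,
                   if (is.null(ch$seed)) "NA" else ch$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample store written by [write_store()]
#' @param path Input path.
#' @return An `ltm_store`.
#' @export
read_store <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- function(key, line) sub(sprintf(".*%s=(\\S+).*", key), "\\1", line)
  traits <- strsplit(meta("traits", hdr[2]), ",")[[1]]
  binary <- meta("binary", hdr[2])
  if (binary == "NA") binary <- NA_character_
  ch_line <- hdr[3]
  seed <- meta("seed", ch_line)
  chain <- ltm_chain(as.integer(meta("n_cycles", ch_line)),
                     as.integer(meta("burn_in", ch_line)),
                     as.integer(meta("thin", ch_line)),
                     seed = if (seed == "NA") NULL else as.integer(seed))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t", check.names = FALSE)
  nt <- length(traits)
  ns <- nrow(df)
  if (ns == 0L) stop("sample store is empty: ", path)
  low <- which(lower.tri(diag(nt), diag = TRUE))
  labs <- lower_tri_labels(traits)
  unpack <- function(prefix, pin_idx = NA) {
    arr <- array(NA_real_, c(nt, nt, ns))
    for (k in seq_along(low)) {
      colname <- paste0(prefix, ".", labs[k])
      pos <- low[k]
      i <- (pos - 1L) %% nt + 1L; j <- (pos - 1L) %/% nt + 1L
      if (colname %in% names(df)) {
        arr[i, j, ] <- arr[j, i, ] <- df[[colname]]
      } else if (!is.na(pin_idx) && i == pin_idx && j == pin_idx) {
        arr[i, j, ] <- 1
      } else {
        stop("corrupt sample store, missing column ", colname)
      }
    }
    arr
  }
  bidx <- if (!is.na(binary)) match(binary, traits) else NA
  G <- if (any(startsWith(names(df), "G."))) unpack("G") else NULL
  R <- unpack("R", pin_idx = bidx)
  new_ltm_store(G = G, R = R, cycle = df$cycle, traits = traits,
                binary = binary, chain = chain)
}
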