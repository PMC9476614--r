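#' Paired epoched dual-EEG container
#'
#' Holds the epoched EEG of both players of one dyad: two
#' trials x channels x samples arrays with a shared time axis, channel
#' labels, per-trial condition labels and a keep-mask. Both players must
#' have identical shape, labels and trial ordering.
#'
#' @param p1,p2 trials x channels x samples numeric arrays.
#' @param sfreq Sampling frequency (Hz).
#' @param ch_names Channel labels (length = 2nd dimension).
#' @param tmin Time (s) of the first sample relative to the visual cue
#'   (default -1).
#' @param conditions data.frame of per-trial labels (needs at least
#'   `tempo_condition` and `familiarity` for the statistics stage).
#' @param keep Logical keep-mask per trial (replaces interactive artifact
#'   rejection; defaults to all `TRUE`).
#' @param pair_id Dyad identifier.
#' @return Object of class `dyad_epochs`.
#' @export
dyad_epochs <- function(p1, p2, sfreq, ch_names = channel_names(),
                        tmin = -1, conditions = NULL, keep = NULL,
                        pair_id = 1L) {
  if (!identical(dim(p1), dim(p2)))
    stop("the two players' arrays must have identical shape")
  if (dim(p1)[2] != length(ch_names))
    stop("channel dimension (", dim(p1)[2], ") does not match `ch_names` (",
         length(ch_names), ")")
  n_tr <- dim(p1)[1]
  if (is.null(keep)) keep <- rep(TRUE, n_tr)
  if (!is.null(conditions) && nrow(conditions) != n_tr)
    stop("`conditions` must have one row per trial")
  structure(list(p1 = p1, p2 = p2, sfreq = sfreq, ch_names = ch_names,
                 tmin = tmin, conditions = conditions, keep = keep,
                 pair_id = pair_id),
            class = "dyad_epochs")
}

#' @export
print.dyad_epochs <- function(x, ...) {
  d <- dim(x$p1)
  cat("<dyad_epochs> pair", x$pair_id, ":", d[1], "trials x", d[2],
      "channels x", d[3], "samples @", x$sfreq, "Hz, t0 =", x$tmin, "s;",
      sum(x$keep), "trials kept\n")
  invisible(x)
}

#' Time axis of an epoch container
#' @param epochs `dyad_epochs` object.
#' @return Numeric vector of sample times (s).
#' @export
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$p1)[3]) - 1) / epochs$sfreq
}

#' Write a dyad epoch container to disk
#'
#' Self-describing directory bundle: `meta.json` carries the sampling
#' rate, channel labels, time axis origin, array shapes, condition table
#' and keep-mask; the two players' arrays are stored as flat little-endian
#' float64 files. The round trip through [read_dyad_epochs()] is lossless.
#'
#' @param epochs `dyad_epochs` object.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dyad_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "dyad_epochs"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "duetIBS-epochs-v1", sfreq = epochs$sfreq,
               ch_names = epochs$ch_names, tmin = epochs$tmin,
               dims = dim(epochs$p1), keep = epochs$keep,
               pair_id = epochs$pair_id, conditions = epochs$conditions)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (pl in c("p1", "p2")) {
    con <- file(file.path(path, paste0(pl, ".bin")), "wb")
    writeBin(as.vector(epochs[[pl]]), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a dyad epoch container from disk
#'
#' @param path Directory written by [write_dyad_epochs()].
#' @return `dyad_epochs` object.
#' @export
read_dyad_epochs <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not an epoch container: missing ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  arr <- list()
  for (pl in c("p1", "p2")) {
    f <- file.path(path, paste0(pl, ".bin"))
    if (!file.exists(f) || file.info(f)$size != 8 * n)
      stop("truncated or missing array file: ", f, " (expected ",
           8 * n, " bytes)")
    con <- file(f, "rb")
    arr[[pl]] <- array(readBin(con, "double", n, size = 8,
                               endian = "little"), dims)
    close(con)
  }
  cond <- meta$conditions
  if (!is.null(cond)) cond <- as.data.frame(cond, stringsAsFactors = FALSE)
  dyad_epochs(arr$p1, arr$p2, sfreq = meta$sfreq,
              ch_names = meta$ch_names, tmin = meta$tmin,
              conditions = cond, keep = meta$keep, pair_id = meta$pair_id)
}

#' Import epochs from a supported container
#'
#' Thin reader front end. The native format is the directory bundle of
#' [write_dyad_epochs()]; further formats can be plugged in by adding a
#' reader.
#'
#' @param path Container path.
#' @param format Container format (only `"native"` ships with the
#'   package).
#' @return Validated `dyad_epochs` object.
#' @export
import_epochs <- function(path, format = c("native")) {
  format <- match.arg(format)
  switch(format, native = read_dyad_epochs(path))
}
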