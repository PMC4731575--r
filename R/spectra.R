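# MGF (Mascot Generic Format) input/output and tolerance-based matching of
# observed centroided peaks to theoretical fragment ions.

#' Construct an MS/MS spectrum
#'
#' @param title Spectrum title.
#' @param pepmass Precursor m/z (Da), > 0.
#' @param charge Precursor charge, integer >= 1.
#' @param peaks Two-column matrix or data.frame of (mz, intensity); peaks are
#'   stored sorted by m/z, intensities must be non-negative.
#' @param extra Named character vector of additional MGF headers to preserve.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(title, pepmass, charge, peaks, extra = character(0)) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) && any(peaks[, "intensity"] < 0))
    stop("negative intensity")
  if (!is.finite(pepmass) || pepmass <= 0) stop("precursor m/z must be > 0")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("precursor charge must be >= 1")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(title = title, pepmass = pepmass, charge = charge,
                 peaks = peaks, extra = extra),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: precursor %.4f m/z (%d+), %d peaks\n",
              x$title, x$pepmass, x$charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with PEPMASS, CHARGE (the "2+"
#' convention) and TITLE headers; unknown headers are preserved and written
#' back by [write_mgf()]. Malformed blocks raise an error naming the line.
#'
#' @param path MGF file path.
#' @return A list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  block_no <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      block_no <- block_no + 1L
      start_line <- i
      title <- sprintf("spectrum_%d", block_no)
      pepmass <- NA_real_
      charge <- NA_integer_
      extra <- character(0)
      mz <- numeric(0)
      int <- numeric(0)
      i <- i + 1L
      repeat {
        if (i > n) stop("unterminated MGF block starting at line ", start_line)
        line <- trimws(lines[i])
        if (line == "END IONS") break
        if (line == "") { i <- i + 1L; next }
        if (grepl("=", line, fixed = TRUE)) {
          key <- toupper(sub("=.*$", "", line))
          val <- sub("^[^=]*=", "", line)
          if (key == "TITLE") title <- val
          else if (key == "PEPMASS") {
            pepmass <- as.numeric(strsplit(trimws(val), "\\s+")[[1]][1])
            if (is.na(pepmass)) stop("bad PEPMASS at line ", i)
          } else if (key == "CHARGE") {
            v <- trimws(val)
            sign <- if (grepl("-$", v)) -1L else 1L
            num <- as.integer(sub("[+-]$", "", v))
            if (is.na(num)) stop("bad CHARGE at line ", i)
            charge <- sign * num
          } else extra[key] <- val
        } else {
          f <- strsplit(line, "\\s+")[[1]]
          v <- suppressWarnings(as.numeric(f))
          if (length(v) < 2L || anyNA(v[1:2]))
            stop("malformed peak line at line ", i, ": '", line, "'")
          mz <- c(mz, v[1])
          int <- c(int, v[2])
        }
        i <- i + 1L
      }
      if (is.na(pepmass))
        stop("block '", title, "' (line ", start_line, ") has no PEPMASS")
      if (is.na(charge))
        stop("block '", title, "' (line ", start_line, ") has no CHARGE")
      spectra[[length(spectra) + 1L]] <-
        spectrum(title, pepmass, charge, cbind(mz, int), extra = extra)
    } else if (line != "" && !startsWith(line, "#")) {
      # header junk outside blocks is tolerated silently only if key=value
      if (!grepl("=", line, fixed = TRUE))
        stop("unexpected content outside BEGIN IONS block at line ", i,
             ": '", line, "'")
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' m/z values are written with 8 decimals (lossless well beyond the 6-decimal
#' contract); extra headers are preserved.
#'
#' @param spectra A list of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.8f", sp$pepmass), con)
    writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (length(sp$extra))
      writeLines(paste0(names(sp$extra), "=", sp$extra), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.8f %.8g", sp$peaks[, "mz"],
                         sp$peaks[, "intensity"]), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Match observed peaks to theoretical fragment ions
#'
#' Greedy nearest matching under a dual tolerance: for each theoretical m/z
#' the window is the tighter of `tol_ppm` (relative) and `tol_da` (absolute;
#' default 0.01 Da, the working accuracy of high-resolution Orbitrap MS/MS).
#' Candidate pairs are assigned in order of increasing |error| (ties toward
#' lower observed m/z); each observed peak and each theoretical fragment is
#' used at most once.
#'
#' @param spec A [spectrum()].
#' @param fragments data.frame from [theoretical_fragments()] (any data.frame
#'   with an `mz` column works).
#' @param tol_ppm Relative tolerance in ppm (> 0).
#' @param tol_da Absolute tolerance cap in Da (> 0).
#' @return data.frame: the matched fragment rows plus `observed_mz`,
#'   `error_da`, `error_ppm` (signed, observed - theoretical) and `intensity`.
#' @export
match_peaks <- function(spec, fragments, tol_ppm = 10, tol_da = 0.01) {
  stopifnot(tol_ppm > 0, tol_da > 0)
  empty <- cbind(fragments[0, , drop = FALSE],
                 data.frame(observed_mz = numeric(0), error_da = numeric(0),
                            error_ppm = numeric(0), intensity = numeric(0)))
  if (nrow(fragments) == 0L || nrow(spec$peaks) == 0L) return(empty)
  obs <- spec$peaks[, "mz"]
  theo <- fragments$mz
  tol <- pmin(tol_da, theo * tol_ppm * 1e-6)
  # candidate pairs via interval lookup on the sorted observed axis
  lo <- findInterval(theo - tol[seq_along(theo)], obs) + 1L
  hi <- findInterval(theo + tol[seq_along(theo)], obs)
  cand_f <- integer(0); cand_o <- integer(0)
  for (k in seq_along(theo)) {
    if (lo[k] <= hi[k]) {
      idx <- lo[k]:hi[k]
      cand_f <- c(cand_f, rep.int(k, length(idx)))
      cand_o <- c(cand_o, idx)
    }
  }
  if (!length(cand_f)) return(empty)
  err <- obs[cand_o] - theo[cand_f]
  ord <- order(abs(err), obs[cand_o])
  used_o <- logical(length(obs))
  used_f <- logical(length(theo))
  keep <- logical(length(ord))
  for (r in ord) {
    f <- cand_f[r]; o <- cand_o[r]
    if (!used_f[f] && !used_o[o]) {
      used_f[f] <- TRUE
      used_o[o] <- TRUE
      keep[r] <- TRUE
    }
  }
  sel <- which(keep)
  out <- fragments[cand_f[sel], , drop = FALSE]
  out$observed_mz <- obs[cand_o[sel]]
  out$error_da <- err[sel]
  out$error_ppm <- err[sel] / theo[cand_f[sel]] * 1e6
  out$intensity <- spec$peaks[cand_o[sel], "intensity"]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a peak-annotation table as TSV
#'
#' @param matches data.frame from [match_peaks()].
#' @param title Spectrum title recorded in the first column.
#' @param path Output path.
#' @export
write_annotation_tsv <- function(matches, title, path) {
  out <- data.frame(spectrum = title, ion = matches$label,
                    theoretical_mz = matches$mz,
                    observed_mz = matches$observed_mz,
                    error_ppm = matches$error_ppm,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
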