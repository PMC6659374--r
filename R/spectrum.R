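#' Construct an NMR spectrum object
#'
#' A frequency-domain 1H spectrum (real part). The ppm axis is stored in
#' strictly decreasing order, the conventional NMR display orientation;
#' ascending input is reversed (together with the intensities) on
#' construction.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @param frequency_mhz Spectrometer proton frequency in MHz (default 600,
#'   the platform's field strength).
#' @param sample_id Sample identifier.
#' @param metadata Named list of acquisition tags / QC flags.
#' @return An object of class `nmr_spectrum`: a list with elements `ppm`,
#'   `intensity`, `frequency_mhz`, `sample_id`, `metadata`.
#' @examples
#' sp <- nmr_spectrum(seq(10, -0.5, length.out = 64), rnorm(64))
#' sp
#' @export
nmr_spectrum <- function(ppm, intensity, frequency_mhz = 600,
                         sample_id = "sample", metadata = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have the same length")
  if (length(ppm) < 2) stop("a spectrum needs at least 2 points")
  d <- diff(ppm)
  if (all(d > 0)) {       # ascending input: flip to display order
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone")
  }
  if (!is.finite(frequency_mhz) || frequency_mhz <= 0)
    stop("frequency_mhz must be a positive number")
  if (!all(is.finite(intensity)))
    stop("all intensities must be finite")
  structure(list(ppm = ppm, intensity = intensity,
                 frequency_mhz = frequency_mhz,
                 sample_id = as.character(sample_id),
                 metadata = metadata),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.4f .. %.4f ppm @ %g MHz\n",
              x$sample_id, length(x$ppm), x$ppm[1],
              x$ppm[length(x$ppm)], x$frequency_mhz))
  invisible(x)
}

#' Select the points of a spectrum inside a ppm window
#'
#' Windows follow the half-open display convention `[high_ppm, low_ppm)`:
#' a point at exactly `high_ppm` is included, one at exactly `low_ppm` is
#' not, so adjacent windows sharing an edge never double-count a point.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param high_ppm,low_ppm Window edges, `high_ppm > low_ppm`.
#' @return Integer index vector into the spectrum's axis.
#' @export
ppm_window <- function(spectrum, high_ppm, low_ppm) {
  if (high_ppm <= low_ppm) stop("high_ppm must exceed low_ppm")
  which(spectrum$ppm <= high_ppm & spectrum$ppm > low_ppm)
}

#' Read a spectrum from disk
#'
#' Two formats are supported: plain two-column text (ppm, intensity;
#' whitespace or tab separated, `#` comments allowed) and the simple
#' JCAMP-DX dialect with an uncompressed `##XYDATA=(X++(Y..Y))` block
#' (AFFN numbers only; DIF/DUP-compressed files and vendor raw directories
#' are not supported — all time-domain processing happens upstream).
#'
#' @param path File path.
#' @param format `"xy_text"` or `"jcamp"`; `"auto"` sniffs JCAMP by the
#'   leading `##TITLE` record.
#' @param frequency_mhz Fallback spectrometer frequency when the file
#'   carries none. `xy_text` files never carry one; JCAMP files usually do
#'   (`##.OBSERVE FREQUENCY`).
#' @param sample_id Sample id; default the file base name.
#' @return An [nmr_spectrum()] with a decreasing ppm axis.
#' @export
read_spectrum <- function(path, format = c("auto", "xy_text", "jcamp"),
                          frequency_mhz = 600, sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^##TITLE", first)) "jcamp" else "xy_text"
  }
  if (format == "xy_text") {
    lines <- readLines(path, warn = FALSE)
    # optional header comments written by write_spectrum
    fq <- grep("^#\\s*frequency_mhz:", lines, value = TRUE)
    if (length(fq))
      frequency_mhz <- as.numeric(sub("^#\\s*frequency_mhz:\\s*", "", fq[1]))
    sid <- grep("^#\\s*sample_id:", lines, value = TRUE)
    if (length(sid))
      sample_id <- trimws(sub("^#\\s*sample_id:\\s*", "", sid[1]))
    keep <- !grepl("^\\s*(#|$)", lines)
    fields <- strsplit(trimws(lines[keep]), "[\\s,]+", perl = TRUE)
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad))
      stop("parse error in ", path, " at data line ", bad[1],
           ": expected two columns")
    ppm <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
    y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    if (anyNA(ppm) || anyNA(y))
      stop("parse error in ", path, " at data line ",
           which(is.na(ppm) | is.na(y))[1], ": non-numeric value")
    if (is.null(frequency_mhz))
      stop("xy_text carries no spectrometer frequency; supply frequency_mhz")
    return(nmr_spectrum(ppm, y, frequency_mhz, sample_id))
  }
  read_jcamp(path, frequency_mhz, sample_id)
}

read_jcamp <- function(path, frequency_mhz, sample_id) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##\\.?", name, "\\s*="), lines,
                ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  num <- function(name) {
    v <- ldr(name)
    if (is.null(v)) NULL else as.numeric(gsub("[^0-9eE+.-]", "", v))
  }
  freq <- num("OBSERVE FREQUENCY")
  if (is.null(freq) || !is.finite(freq)) {
    if (is.null(frequency_mhz))
      stop("JCAMP file lacks ##.OBSERVE FREQUENCY and no default given")
    freq <- frequency_mhz
  }
  xf <- num("XFACTOR"); if (is.null(xf)) xf <- 1
  yf <- num("YFACTOR"); if (is.null(yf)) yf <- 1
  xunits <- ldr("XUNITS")
  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(start))
    stop("parse error in ", path, ": no ##XYDATA record")
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- end[end > start[1]]
  end <- if (length(end)) end[1] - 1L else length(lines)
  body <- lines[(start[1] + 1L):end]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]+", "", body))))
    stop("parse error in ", path,
         ": compressed (DIF/DUP) XYDATA is not supported")
  x <- numeric(0); y <- numeric(0)
  for (i in seq_along(body)) {
    vals <- as.numeric(strsplit(trimws(body[i]), "[\\s,;]+", perl = TRUE)[[1]])
    if (length(vals) < 2 || anyNA(vals))
      stop("parse error in ", path, " at XYDATA line ", i)
    x <- c(x, vals[1])
    y <- c(y, vals[-1])
  }
  npt <- num("NPOINTS")
  n <- length(y)
  if (!is.null(npt) && is.finite(npt) && npt != n)
    stop("parse error in ", path, ": NPOINTS=", npt,
         " but ", n, " ordinates found")
  firstx <- num("FIRSTX"); lastx <- num("LASTX")
  if (is.null(firstx)) firstx <- x[1] * xf
  if (is.null(lastx)) lastx <- firstx  # degenerate; overwritten below if n>1
  axis <- seq(firstx, lastx, length.out = n)
  # HZ axes are converted to ppm with the observe frequency
  if (!is.null(xunits) && grepl("HZ", toupper(xunits))) axis <- axis / freq
  nmr_spectrum(axis, y * yf, freq, sample_id)
}

#' Write a spectrum as two-column text
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path Output path.
#' @param digits Significant digits (default 17: round-trip exact for
#'   doubles).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, digits = 17) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id: %s", spectrum$sample_id), con)
  writeLines(sprintf("# frequency_mhz: %.6f", spectrum$frequency_mhz), con)
  writeLines(paste(formatC(spectrum$ppm, digits = digits, format = "g"),
                   formatC(spectrum$intensity, digits = digits, format = "g")),
             con)
  invisible(path)
}
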