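#' Seeded lognormal toy population
#'
#' A stand-in population of per-cell protein contents for tests and
#' examples that must not run the full simulator.
#'
#' @param n Number of cells.
#' @param meanlog,sdlog Lognormal parameters (natural-log scale).
#' @param seed RNG seed.
#' @return Numeric vector of length \code{n} (aa).
#' @export
toy_population <- function(n, meanlog = log(3e10), sdlog = 0.35, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Instrument model for synthetic flow-cytometry experiments
#'
#' @param fu_per_aa Affine gain: fluorescence units per amino acid.
#' @param offset Fluorescence offset (fu).
#' @param CV_instrument Multiplicative measurement CV.
#' @param n_events Recorded cells per sample.
#' @return An object of class \code{"instrument_model"}.
#' @export
instrument_model <- function(fu_per_aa = 1e-7, offset = 0,
                             CV_instrument = 0.04, n_events = 30000) {
  stopifnot(fu_per_aa > 0, CV_instrument >= 0, n_events >= 1)
  structure(list(fu_per_aa = fu_per_aa, offset = offset,
                 CV_instrument = CV_instrument,
                 n_events = as.integer(n_events)),
            class = "instrument_model")
}

#' Synthesize a noisy "experimental" fluorescence histogram
#'
#' Emulates a flow-cytometry acquisition from a simulated population:
#' samples \code{n_events} cells, applies the affine instrument response
#' \code{fu = gain * P * (1 + eps) + offset} with multiplicative Gaussian
#' noise \code{eps ~ N(0, CV)}, and bins the readings into 1024 channels
#' spanning the sampled range. Every comparison path of the package is
#' therefore testable without any downloaded dataset; the output is
#' synthetic by construction.
#'
#' @param values Simulated per-cell protein contents (aa); nonempty.
#' @param m An \code{\link{instrument_model}}.
#' @param seed RNG seed (sampling and noise).
#' @return A \code{"protein_histogram"} on the fluorescence scale.
#' @export
synthesize_experiment <- function(values, m = instrument_model(), seed = 7) {
  stopifnot(length(values) >= 1)
  set.seed(seed)
  idx <- sample.int(length(values), m$n_events,
                    replace = m$n_events > length(values))
  P <- values[idx]
  eps <- if (m$CV_instrument > 0)
    stats::rnorm(m$n_events, 0, m$CV_instrument) else numeric(m$n_events)
  fu <- m$fu_per_aa * P * (1 + eps) + m$offset
  origin <- min(fu)
  width <- (max(fu) - origin) / 1024 * (1 + 1e-9)  # max falls in channel 1023
  build_histogram(fu, origin, width, scale = "fluorescence_units")
}

#' Read or write a 1024-channel histogram as CSV
#'
#' The interchange format is a two-column CSV \code{(channel, count)} with
#' channels 0..1023; origin and width travel in a comment-free header row
#' pair (\code{bin_origin}, \code{bin_width}) when written by this package,
#' and default to 0/1 when absent.
#'
#' @param h A \code{"protein_histogram"} (for writing).
#' @param path File path.
#' @return \code{read_histogram_csv}: a \code{"protein_histogram"}.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "protein_histogram"))
  df <- data.frame(channel = 0:1023, count = h$counts)
  attr_line <- sprintf("# scale=%s bin_origin=%.10g bin_width=%.10g",
                       h$scale, h$bin_origin, h$bin_width)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  first <- readLines(path, n = 1)
  origin <- 0; width <- 1; scale <- "fluorescence_units"
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=")[[1]]
      if (parts[1] == "bin_origin") origin <- as.numeric(parts[2])
      if (parts[1] == "bin_width") width <- as.numeric(parts[2])
      if (parts[1] == "scale") scale <- parts[2]
    }
  }
  df <- utils::read.csv(path, skip = skip)
  if (!all(c("channel", "count") %in% names(df)))
    stop("histogram CSV needs columns `channel` and `count`")
  counts <- numeric(1024)
  counts[df$channel + 1L] <- df$count
  protein_histogram(counts, origin, width, scale = scale)
}
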