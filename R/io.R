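#' Read a DEER trace from disk
#'
#' ASCII: two whitespace/comma-separated columns (time, amplitude), comment
#' lines starting with '#'. A time axis whose maximum exceeds 100 is taken
#' to be in nanoseconds and converted to microseconds (the decision is
#' recorded in the trace metadata). Bruker BES3T: a minimal `.DSC`/`.DTA`
#' pair reader for real 1D data (big-endian float64 by default, axis from
#' XMIN/XWID/XPTS). Amplitude is normalized to maximum 1 at load.
#'
#' @param path file path (for BES3T, either member of the pair)
#' @param format "auto" (default, by extension), "ascii" or "bes3t"
#' @return a raw-stage [deer_trace()]
#' @export
read_trace <- function(path, format = c("auto", "ascii", "bes3t")) {
  format <- match.arg(format)
  if (!file.exists(path) &&
      !(format != "ascii" && file.exists(sub("\\.[^.]+$", ".DSC", path))))
    stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(dsc|dta)$", path, ignore.case = TRUE))
      "bes3t" else "ascii"
  if (format == "bes3t") return(read_bes3t(path))
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("time", "amplitude"))
  time <- tab$time
  meta <- list(source = path)
  if (max(time) > 100) {  # ns-scale axis
    time <- time / 1000
    meta$unit_conversion <- "time axis read as ns, converted to us"
  }
  amp <- tab$amplitude / max(tab$amplitude)
  time <- time - time[1]
  deer_trace(time, amp, stage = "raw", metadata = meta)
}

# Minimal Bruker BES3T reader: real 1D dataset, axis from XMIN/XWID/XPTS.
read_bes3t <- function(path) {
  base <- sub("\\.[^.]+$", "", path)
  dsc <- paste0(base, ".DSC")
  dta <- paste0(base, ".DTA")
  if (!file.exists(dsc)) stop("missing descriptor file: ", dsc)
  if (!file.exists(dta)) stop("missing data file: ", dta)
  lines <- readLines(dsc, warn = FALSE)
  get_field <- function(key, default = NULL) {
    m <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (!length(m)) {
      if (is.null(default)) stop("malformed descriptor: missing ", key)
      return(default)
    }
    trimws(sub(paste0("^", key, "\\s+"), "", m[1]))
  }
  xpts <- as.integer(get_field("XPTS"))
  xmin <- as.numeric(get_field("XMIN"))
  xwid <- as.numeric(get_field("XWID"))
  bseq <- get_field("BSEQ", "BIG")
  irfmt <- get_field("IRFMT", "D")
  endian <- if (toupper(bseq) == "BIG") "big" else "little"
  size <- if (toupper(irfmt) == "D") 8L else 4L
  what <- "double"
  n_avail <- file.info(dta)$size / size
  if (n_avail < xpts)
    stop(sprintf(".DTA holds %d values but .DSC declares XPTS = %d",
                 as.integer(n_avail), xpts))
  con <- file(dta, "rb")
  on.exit(close(con))
  y <- readBin(con, what, n = xpts, size = size, endian = endian)
  x <- xmin + xwid * seq(0, xpts - 1) / (xpts - 1)
  meta <- list(source = dta, format = "BES3T")
  xunit <- get_field("XUNI", "'ns'")
  if (grepl("ns", xunit) || max(x) > 100) {
    x <- x / 1000
    meta$unit_conversion <- "time axis read as ns, converted to us"
  }
  deer_trace(x - x[1], y / max(y), stage = "raw", metadata = meta)
}

#' Write a DEER trace as two-column ASCII
#'
#' @param trace a [deer_trace()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "deer_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# DEER trace written by deerfit",
               sprintf("# stage: %s", trace$stage),
               "# columns: time_us amplitude"), con)
  utils::write.table(
    data.frame(time = sprintf("%.9g", trace$time),
               amplitude = sprintf("%.9g", trace$amplitude)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CW spectrum from two-column ASCII
#'
#' Columns: field (Gauss), first-derivative intensity; '#' comments. A
#' decreasing field axis is reversed (noted in a message).
#'
#' @param path file path
#' @return a [cw_spectrum()]
#' @export
read_cw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("field", "intensity"))
  field <- tab$field; intensity <- tab$intensity
  if (all(diff(field) < 0)) {
    message("decreasing field axis reversed to ascending")
    field <- rev(field); intensity <- rev(intensity)
  }
  db <- diff(field)
  if (any(db <= 0) || max(abs(db - db[1])) > 1e-6 * abs(db[1]))
    stop("non-uniform field grid at indices: ",
         paste(utils::head(which(abs(db - db[1]) > 1e-6 * abs(db[1]))),
               collapse = ", "))
  cw_spectrum(field, intensity)
}

#' Write / read a distance distribution as two-column ASCII
#'
#' @param dist a [distance_distribution()]
#' @param path file path
#' @return invisibly `path` (write); a [distance_distribution()] (read)
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# distance distribution written by deerfit",
               "# columns: r_nm density_per_nm"), con)
  utils::write.table(
    data.frame(r = sprintf("%.9g", dist$r),
               d = sprintf("%.12g", dist$density)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("r", "density"))
  distance_distribution(tab$r, tab$density, normalize = FALSE)
}

#' Write a JSON analysis report
#'
#' Serializes a [analyze_deer()] result: fitted components and fractions,
#' background parameters, regularization choice, BIC table, noise estimate
#' and any background-stability flags.
#'
#' @param analysis a `deer_analysis` object
#' @param path output path
#' @return invisibly, the report list
#' @export
write_report <- function(analysis, path) {
  stopifnot(inherits(analysis, "deer_analysis"))
  rep <- list(
    package = "deerfit",
    version = as.character(utils::packageVersion("deerfit")),
    seed = analysis$rng_seed,
    background = analysis$background[c("k", "lambda", "d")],
    alpha = analysis$tikhonov$alpha,
    alpha_chosen_by = analysis$tikhonov$chosen_by,
    alpha_lcurve = analysis$tikhonov$alpha_lcurve,
    alpha_loocv = analysis$tikhonov$alpha_loocv,
    noise = analysis$noise,
    components = as.data.frame(analysis$fit$components),
    rmsd = analysis$fit$rmsd,
    bic_table = analysis$bic_table,
    stability = if (!is.null(analysis$stability))
      as.data.frame(analysis$stability) else NULL,
    uncertainty = analysis$uncertainty)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(rep)
}

#' Check a report file against the expected schema
#'
#' Light structural validation: required keys present, components table
#' well-formed, fractions summing to 1.
#'
#' @param path report JSON path
#' @return TRUE (invisibly) or an error describing the violation
#' @export
validate_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("package", "version", "seed", "background", "alpha",
            "components", "rmsd", "bic_table")
  miss <- setdiff(need, names(rep))
  if (length(miss)) stop("report missing keys: ", paste(miss, collapse = ", "))
  comp <- rep$components
  if (!all(c("center", "fwhm", "fraction") %in% names(comp)))
    stop("components table malformed")
  if (abs(sum(comp$fraction) - 1) > 1e-6)
    stop("component fractions do not sum to 1")
  invisible(TRUE)
}
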