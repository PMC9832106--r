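#' Physiological acceptance box for pre-resection outputs
#'
#' Clinical plausibility ranges applied to the simulated pre-resection
#' outputs.  Defaults: MAP 50-130 mmHg, CO 3-10 L/min, portal pressure
#' 3-20 mmHg, portocaval gradient 1-14 mmHg.  Intervals are closed:
#' boundary values are retained.
#'
#' @param MAP,CO,P_pv,PCG length-2 numeric ranges \code{c(min, max)}
#' @return object of class \code{filter_bounds}
#' @export
filter_bounds <- function(MAP = c(50, 130), CO = c(3, 10),
                          P_pv = c(3, 20), PCG = c(1, 14)) {
  b <- list(MAP = MAP, CO = CO, P_pv = P_pv, PCG = PCG)
  for (nm in names(b)) {
    r <- b[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid range for ", nm, ": need finite min < max")
  }
  structure(b, class = "filter_bounds")
}

#' @export
print.filter_bounds <- function(x, ...) {
  cat("<filter_bounds>\n")
  for (nm in names(x))
    cat(sprintf("  %-5s [%g, %g]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

# resolve the column holding a filtered quantity: plain name or pre_ prefix
filter_column <- function(outputs, nm) {
  if (nm %in% names(outputs)) return(outputs[[nm]])
  pre <- paste0("pre_", nm)
  if (pre %in% names(outputs)) return(outputs[[pre]])
  stop("missing output column: ", nm, " (or ", pre, ")")
}

#' Apply the physiological filter
#'
#' A simulated patient is retained iff every filtered pre-resection
#' output lies inside its closed interval.  The filter is applied to
#' pre-resection outputs only; post-resection outputs are carried along
#' untouched.
#'
#' @param outputs data frame containing the filtered quantities (columns
#'   \code{MAP}, \code{CO}, \code{P_pv}, \code{PCG}, or the same with a
#'   \code{pre_} prefix)
#' @param bounds a \code{\link{filter_bounds}}
#' @return logical retention mask, one element per row of \code{outputs}
#' @export
apply_filter <- function(outputs, bounds = filter_bounds()) {
  mask <- rep(TRUE, nrow(outputs))
  for (nm in names(bounds)) {
    v <- filter_column(outputs, nm)
    mask <- mask & !is.na(v) & v >= bounds[[nm]][1] & v <= bounds[[nm]][2]
  }
  mask
}

#' Assemble the virtual population
#'
#' Binds retained input rows with their pre- and post-resection outputs
#' and records provenance (seed, filter bounds, retention counts).
#'
#' @param inputs cohort input rows (data frame, ten input columns)
#' @param outputs evaluated outputs (\code{pre_*}/\code{post_*} columns),
#'   row-aligned with \code{inputs}
#' @param mask logical retention mask from \code{\link{apply_filter}}
#' @param bounds the bounds used
#' @param seed the generating seed (provenance)
#' @param model_version free-form model/config identifier (provenance)
#' @return data frame of class \code{virtual_population} with attributes
#'   \code{n_total}, \code{n_retained}, \code{provenance}
#' @export
assemble_population <- function(inputs, outputs, mask,
                                bounds = filter_bounds(),
                                seed = NA_integer_,
                                model_version = "hepasens-0d") {
  if (nrow(inputs) != nrow(outputs) || nrow(inputs) != length(mask))
    stop("misaligned rows between inputs, outputs and mask")
  pop <- cbind(inputs[mask, , drop = FALSE],
               outputs[mask, , drop = FALSE])
  rownames(pop) <- NULL
  structure(pop, class = c("virtual_population", "data.frame"),
            n_total = nrow(inputs), n_retained = sum(mask),
            provenance = list(seed = seed, bounds = unclass(bounds),
                              model_version = model_version,
                              created = "hepasens"))
}

#' @export
print.virtual_population <- function(x, ...) {
  cat("<virtual_population>", attr(x, "n_retained"), "of",
      attr(x, "n_total"), "simulated patients retained (",
      round(100 * attr(x, "n_retained") / max(attr(x, "n_total"), 1), 1),
      "%)\n")
  invisible(x)
}

#' Write / read a virtual population (CSV + JSON provenance sidecar)
#' @param pop a \code{virtual_population}
#' @param path CSV path
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  meta <- c(attr(pop, "provenance"),
            list(n_total = attr(pop, "n_total"),
                 n_retained = attr(pop, "n_retained")))
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(sub("\\.csv$", "", path),
                                     "_meta.json"), simplifyVector = TRUE)
  structure(df, class = c("virtual_population", "data.frame"),
            n_total = meta$n_total, n_retained = meta$n_retained,
            provenance = meta[setdiff(names(meta),
                                      c("n_total", "n_retained"))])
}

#' Median comparison against a reference cohort
#'
#' Per output and phase, the absolute difference between the population
#' median and the reference median, also expressed as a percentage of
#' the reference median.
#'
#' @param population,reference data frames with \code{pre_*} and
#'   \code{post_*} output columns
#' @return data frame with one row per output/phase
#' @export
compare_distributions <- function(population, reference) {
  cols <- c(paste0("pre_", output_names()), paste0("post_", output_names()))
  out <- lapply(cols, function(cn) {
    if (!cn %in% names(population) || !cn %in% names(reference))
      stop("missing output column: ", cn)
    a <- population[[cn]]; b <- reference[[cn]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("empty output set for ", cn)
    ma <- stats::median(a); mb <- stats::median(b)
    data.frame(output = sub("^(pre|post)_", "", cn),
               phase = ifelse(grepl("^pre_", cn), "pre-hpx", "post-hpx"),
               median = ma, ref_median = mb,
               abs_diff = abs(ma - mb),
               pct_diff = 100 * abs(ma - mb) / abs(mb))
  })
  do.call(rbind, out)
}

#' Retained-region summary of the filtered inputs
#'
#' Per-input retained ranges plus pairwise occupancy grids (and their
#' convex hulls) for selected input couples; the defaults are the two
#' couples whose joint distribution the filter visibly carves
#' (left-ventricular elastances, and the baseline LV elastance against
#' the other-organ resistance).  The result doubles as the admissible
#' region of the reduced calibration strategy.
#'
#' @param population a \code{virtual_population} (or any data frame with
#'   the input columns)
#' @param pairs list of length-2 character vectors of input names
#' @param grid_n number of occupancy bins per axis
#' @return object of class \code{admissible_region}
#' @export
filtered_input_summary <- function(population,
                                   pairs = list(c("Ea_LV", "Eb_LV"),
                                                c("Eb_LV", "R_OO")),
                                   grid_n = 20) {
  df <- as.data.frame(population)
  if (!nrow(df)) stop("empty population")
  ins <- intersect(input_names(), names(df))
  ranges <- vapply(df[ins], range, numeric(2))
  grids <- lapply(pairs, function(pr) {
    x <- df[[pr[1]]]; y <- df[[pr[2]]]
    bx <- seq(min(x), max(x), length.out = grid_n + 1)
    by <- seq(min(y), max(y), length.out = grid_n + 1)
    ix <- pmin(findInterval(x, bx, rightmost.closed = TRUE), grid_n)
    iy <- pmin(findInterval(y, by, rightmost.closed = TRUE), grid_n)
    counts <- matrix(0L, grid_n, grid_n)
    for (k in seq_along(ix))
      counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
    hull <- grDevices::chull(x, y)
    list(pair = pr, breaks_x = bx, breaks_y = by, counts = counts,
         hull = cbind(x = x[hull], y = y[hull]))
  })
  names(grids) <- vapply(pairs, paste, "", collapse = ":")
  structure(list(ranges = ranges, grids = grids, n = nrow(df)),
            class = "admissible_region")
}

#' @export
print.admissible_region <- function(x, ...) {
  cat("<admissible_region> from", x$n, "retained patients;",
      length(x$grids), "pairwise occupancy grids\n")
  invisible(x)
}

#' Membership test in the filtered admissible region
#'
#' TRUE iff every coordinate lies inside its retained range and every
#' pairwise occupancy cell containing the point is occupied.
#'
#' @param region an \code{\link{filtered_input_summary}} result
#' @param params named numeric (only the inputs appearing in the region
#'   are checked)
#' @export
in_admissible_region <- function(region, params) {
  for (nm in colnames(region$ranges)) {
    if (!nm %in% names(params)) next
    v <- params[[nm]]
    if (v < region$ranges[1, nm] || v > region$ranges[2, nm])
      return(FALSE)
  }
  for (g in region$grids) {
    if (!all(g$pair %in% names(params))) next
    x <- params[[g$pair[1]]]; y <- params[[g$pair[2]]]
    n <- nrow(g$counts)
    ix <- pmin(pmax(findInterval(x, g$breaks_x, rightmost.closed = TRUE),
                    1L), n)
    iy <- pmin(pmax(findInterval(y, g$breaks_y, rightmost.closed = TRUE),
                    1L), n)
    if (g$counts[ix, iy] == 0L) return(FALSE)
  }
  TRUE
}
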