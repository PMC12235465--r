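#' Up / down / stable trend of a time series of region statistics
#'
#' The trend is the sign of the relative change between the first and last
#' timepoints, r = (last - first) / first, with |r| <= band counting as
#' stable (boundary inclusive). First-to-last is used rather than a
#' regression slope: the framework compares the initial and final states,
#' and with 2-3 timepoints a slope adds nothing.
#'
#' @param times Ascending numeric timepoints (>= 2).
#' @param values The statistic at each timepoint; the first must be > 0.
#' @param band Stability half-band on the relative change (default 0.10).
#' @return A list with `trend` (`"up"`, `"down"` or `"stable"`) and
#'   `relative_change`.
#' @examples
#' extract_trend(c(0, 1, 3), c(100, 60, 40))   # down, r = -0.6
#' @export
extract_trend <- function(times, values, band = 0.10) {
  if (length(times) < 2)
    stop("insufficient timepoints: need at least 2")
  stopifnot(length(values) == length(times), !is.unsorted(times))
  if (!is.finite(values[1]) || values[1] <= 0)
    stop("undefined baseline: first value must be positive")
  r <- (values[length(values)] - values[1]) / values[1]
  trend <- if (abs(r) <= band) "stable" else if (r > 0) "up" else "down"
  list(trend = trend, relative_change = r)
}

#' Joint SAXS / micro-CT / XRF trend triplet
#'
#' @param saxs,ct,xrf Trend labels (`"up"`, `"down"`, `"stable"`).
#' @param relative_changes Optional named numeric vector of the three
#'   relative changes.
#' @param element_role Role of the element whose XRF trend is used:
#'   `"immobile"` (tracer, e.g. Ce), `"mobile"` (nutrient, e.g. P) or
#'   `"unspecified"`.
#' @return An object of class `trend_triplet`.
#' @export
trend_triplet <- function(saxs, ct, xrf, relative_changes = NULL,
                          element_role = c("unspecified", "immobile", "mobile")) {
  lv <- c("up", "down", "stable")
  saxs <- match.arg(saxs, lv); ct <- match.arg(ct, lv); xrf <- match.arg(xrf, lv)
  structure(list(saxs = saxs, ct = ct, xrf = xrf,
                 relative_changes = relative_changes,
                 element_role = match.arg(element_role)),
            class = "trend_triplet")
}

#' @export
print.trend_triplet <- function(x, ...) {
  cat(sprintf("trend_triplet: SAXS %s, CT %s, XRF %s (%s element)\n",
              x$saxs, x$ct, x$xrf, x$element_role))
  invisible(x)
}

# the process -> (SAXS, CT, XRF) signature table
.PROCESS_RULES <- list(
  aggregation  = c(saxs = "down", ct = "up",     xrf = "stable"),
  dispersion   = c(saxs = "up",   ct = "down",   xrf = "stable"),
  dissolution  = c(saxs = "down", ct = "stable", xrf = "stable"),
  translocation = c(saxs = "down", ct = "down",  xrf = "down")
)

#' Classify the nanoparticle process from a trend triplet
#'
#' Matches the triplet against the four signatures: aggregation (SAXS
#' down, CT up, XRF stable -- larger clusters absorb more but scatter at
#' smaller angles), dispersion (SAXS up, CT down, XRF stable -- separated
#' clusters scatter more strongly while attenuation per voxel falls),
#' dissolution (SAXS down, CT stable, XRF stable -- particulate structure
#' is lost but the immobile tracer stays put), and translocation (all
#' three down -- material leaves the region). Every matching rule is
#' returned; the signatures are not claimed to partition all possible
#' triplets, so the result may be empty.
#'
#' The XRF trend should be that of the immobile tracer element; the mobile
#' nutrient's decline accompanies dissolution and is reported separately,
#' not used to veto it.
#'
#' @param triplet A [trend_triplet()].
#' @return An object of class `process_call` with `labels` (possibly
#'   empty), `matched_rules` and `confidence_note`.
#' @examples
#' classify_process(trend_triplet("down", "stable", "stable"))  # dissolution
#' @export
classify_process <- function(triplet) {
  stopifnot(inherits(triplet, "trend_triplet"))
  obs <- c(saxs = triplet$saxs, ct = triplet$ct, xrf = triplet$xrf)
  hits <- names(Filter(function(rule) all(rule == obs), .PROCESS_RULES))
  note <- if (length(hits) == 0)
    "inconsistent with framework: no process signature matches"
  else if (length(hits) > 1)
    "ambiguous: multiple process signatures match"
  else
    sprintf("matches the %s signature", hits)
  structure(list(labels = hits,
                 matched_rules = .PROCESS_RULES[hits],
                 confidence_note = note),
            class = "process_call")
}

#' @export
print.process_call <- function(x, ...) {
  lab <- if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)"
  cat(sprintf("process_call: %s -- %s\n", lab, x$confidence_note))
  invisible(x)
}

#' End-to-end multimodal classification of a region
#'
#' Computes, per timepoint, the mean of each modality's signal over the
#' region of interest -- total-scattering map value for SAXS, gray level
#' inside the automatically segmented nanoparticle region for micro-CT,
#' element-map intensity for XRF -- extracts the three first-to-last
#' trends, and matches them against the process signatures.
#'
#' @param saxs_maps List of [feature_map()] (total scattering), one per
#'   timepoint.
#' @param volumes List of [volume3d()], one per timepoint.
#' @param xrf_maps List of [element_map()], one per timepoint; should be
#'   the immobile tracer element (see [classify_process()]).
#' @param region_mask Logical matrix over the SAXS/XRF map grid selecting
#'   the region of interest (e.g. the infiltrated area); the CT statistic
#'   uses the volume's own nanoparticle segmentation.
#' @param times Numeric timepoints (e.g. days), ascending.
#' @param band Stability half-band passed to [extract_trend()].
#' @return A list with `call` (a `process_call`), `triplet` and
#'   `evidence`, a data frame of the per-timepoint statistics.
#' @export
correlate_case <- function(saxs_maps, volumes, xrf_maps, region_mask, times,
                           band = 0.10) {
  n <- length(times)
  if (n < 2) stop("insufficient timepoints: need at least 2")
  stopifnot(length(saxs_maps) == n, length(volumes) == n,
            length(xrf_maps) == n, is.logical(region_mask))
  saxs_stat <- vapply(saxs_maps, function(m)
    mean(m$values[region_mask], na.rm = TRUE), numeric(1))
  ct_stat <- vapply(volumes, function(v) {
    leaf <- segment_leaf(v)
    seg <- segment_np(v, leaf)
    mean(v$gray[seg$np_mask])
  }, numeric(1))
  xrf_stat <- vapply(xrf_maps, function(m)
    mean(m$intensity[region_mask]), numeric(1))
  tr_s <- extract_trend(times, saxs_stat, band)
  tr_c <- extract_trend(times, ct_stat, band)
  tr_x <- extract_trend(times, xrf_stat, band)
  trip <- trend_triplet(tr_s$trend, tr_c$trend, tr_x$trend,
                        relative_changes = c(saxs = tr_s$relative_change,
                                             ct = tr_c$relative_change,
                                             xrf = tr_x$relative_change),
                        element_role = "immobile")
  list(call = classify_process(trip), triplet = trip,
       evidence = data.frame(time = times, saxs = saxs_stat,
                             ct = ct_stat, xrf = xrf_stat))
}

#' Plain-text report of a multimodal classification
#'
#' @param case Result of [correlate_case()].
#' @param path Optional file to write to; otherwise returned as a
#'   character vector.
#' @export
report_case <- function(case, path = NULL) {
  ev <- case$evidence
  lines <- c(
    "multimodal nanoparticle-fate classification",
    sprintf("trends: SAXS %s (%+.3f), CT %s (%+.3f), XRF %s (%+.3f)",
            case$triplet$saxs, case$triplet$relative_changes["saxs"],
            case$triplet$ct, case$triplet$relative_changes["ct"],
            case$triplet$xrf, case$triplet$relative_changes["xrf"]),
    sprintf("call: %s", if (length(case$call$labels))
      paste(case$call$labels, collapse = ", ") else "(none)"),
    case$call$confidence_note,
    "", "evidence:",
    utils::capture.output(print(ev, row.names = FALSE)))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
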