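# ---------------------------------------------------------------------------
# Quantitative outputs: molecule counts binned along an axis (the spatial
# distribution plots for dendrite runs) and time series synchronized with
# simulation checkpoints. Molecules are binned by the barycenter of the
# element that holds them, which keeps the histograms deterministic and
# independent of the render-point RNG.
# ---------------------------------------------------------------------------

#' Axial distribution of molecules
#'
#' Projects the barycenter of every element in the restriction onto `axis`
#' and accumulates the element's molecule count into half-open bins
#' `[edge_i, edge_{i+1})` (the last bin is closed). Restricting to an ROI
#' filters elements first — e.g. the `"shaft"` ROI of a spiny dendrite
#' excludes molecules trapped in spines.
#'
#' @param state A `sim_state`.
#' @param species Species id.
#' @param axis Unit direction of the axis (length-3).
#' @param origin Axis origin (projections are relative to it).
#' @param bins Number of bins (>= 1), or a numeric vector of bin edges.
#' @param restriction Compartment/ROI name or `NULL` (all tets).
#' @return An `axial_histogram`: list with `bin_edges`, `counts`,
#'   `restriction`, `t`.
#' @export
axial_distribution <- function(state, species, axis = c(1, 0, 0),
                               origin = c(0, 0, 0), bins = 50L,
                               restriction = NULL) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must have nonzero length")
  axis <- axis / nrm
  sc <- if (is.null(restriction))
    list(kind = "tet", elems = seq_len(state$ntet))
  else .resolve_scope(state, restriction)
  bc <- if (sc$kind == "tet")
    state$mesh$tet_barycenters[sc$elems, , drop = FALSE]
  else state$mesh$tri_barycenters[sc$elems, , drop = FALSE]
  pos <- (bc[, 1] - origin[1]) * axis[1] + (bc[, 2] - origin[2]) * axis[2] +
    (bc[, 3] - origin[3]) * axis[3]
  counts <- element_counts(state, sc, species)
  if (length(bins) == 1L) {
    if (bins < 1) stop("bins must be >= 1")
    rng <- range(pos)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1e-12)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    edges <- as.numeric(bins)
  }
  bin <- findInterval(pos, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= length(edges) - 1L
  hist_counts <- vapply(seq_len(length(edges) - 1L), function(b)
    sum(counts[keep & bin == b]), 0.0)
  structure(list(bin_edges = edges, counts = hist_counts,
                 species = species, restriction = restriction,
                 axis = axis, origin = origin, t = sim_time(state)),
            class = "axial_histogram")
}

#' Axial spread of molecules
#'
#' Standard deviation of the axis projection of molecule positions
#' (element barycenters weighted by counts) within a restriction; the
#' summary used to compare diffusion across spine densities.
#'
#' @inheritParams axial_distribution
#' @return Standard deviation in metres (`NA` when the restriction holds no
#'   molecules).
#' @export
axial_spread <- function(state, species, axis = c(1, 0, 0),
                         origin = c(0, 0, 0), restriction = NULL) {
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  sc <- if (is.null(restriction))
    list(kind = "tet", elems = seq_len(state$ntet))
  else .resolve_scope(state, restriction)
  bc <- state$mesh$tet_barycenters[sc$elems, , drop = FALSE]
  pos <- (bc[, 1] - origin[1]) * axis[1] + (bc[, 2] - origin[2]) * axis[2] +
    (bc[, 3] - origin[3]) * axis[3]
  w <- element_counts(state, sc, species)
  n <- sum(w)
  if (n == 0) return(NA_real_)
  mu <- sum(w * pos) / n
  sqrt(sum(w * (pos - mu)^2) / n)
}

#' Record synchronized time series from one or more simulations
#'
#' Runs all simulations through shared checkpoints (see [sync_run()]) and
#' records counts (or molar concentrations) per scope and species.
#'
#' @param sims List of `sim_state`s (a single state is accepted).
#' @param scopes Character vector of compartment/patch/ROI names.
#' @param species Character vector of species ids.
#' @param t_end End time (s).
#' @param dt_update Checkpoint interval (s).
#' @param measure `"count"` or `"conc"` (molar; volume scopes only).
#' @return List of `time_series` objects (one per simulation): data.frames
#'   with a `time` column and one column per scope x species.
#' @export
record_time_series <- function(sims, scopes, species, t_end, dt_update,
                               measure = c("count", "conc")) {
  measure <- match.arg(measure)
  if (inherits(sims, "sim_state")) sims <- list(sims)
  fn <- if (measure == "count") sim_count else sim_conc
  recorder <- function(state, time) {
    vals <- unlist(lapply(scopes, function(sc) {
      v <- fn(state, sc, species)
      stats::setNames(v, paste(sc, species, sep = "."))
    }))
    vals
  }
  run <- sync_run(sims, t_end, dt_update, recorder)
  lapply(run$records, function(m) {
    df <- data.frame(time = run$times, m, check.names = FALSE)
    class(df) <- c("time_series", "data.frame")
    df
  })
}

#' Plot recorded outputs to an image file
#'
#' Renders time series as line plots and axial histograms as stacked
#' per-run distribution panels. Purely presentational: all quantitative
#' checks belong on the underlying numbers.
#'
#' @param records A `time_series`, an `axial_histogram`, or a list of them
#'   (stacked as one row per record).
#' @param path Output file; the device is chosen from the extension
#'   (`.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
plot_outputs <- function(records, path) {
  if (inherits(records, "time_series") ||
      inherits(records, "axial_histogram"))
    records <- list(records)
  if (!length(records)) stop("no records to plot")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = 800,
                                   height = 260 * length(records))
  else if (ext == "pdf") grDevices::pdf(path, width = 8,
                                        height = 2.6 * length(records))
  else stop("unsupported plot format: .", ext)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(records), 1L), mar = c(4, 4, 2, 1))
  for (rec in records) {
    if (inherits(rec, "axial_histogram")) {
      mid <- (utils::head(rec$bin_edges, -1L) +
                utils::tail(rec$bin_edges, -1L)) / 2
      graphics::plot(mid, rec$counts, type = "h", lwd = 3,
                     xlab = "axial position (m)", ylab = "molecules",
                     main = sprintf("%s, t = %.4g s", rec$species, rec$t))
    } else {
      cols <- setdiff(names(rec), "time")
      graphics::matplot(rec$time, as.matrix(rec[cols]), type = "l",
                        lty = 1, xlab = "time (s)", ylab = "value")
      graphics::legend("topright", legend = cols, lty = 1,
                       col = seq_along(cols), cex = 0.7, bty = "n")
    }
  }
  invisible(path)
}
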