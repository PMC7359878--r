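#' Construct a connectome
#'
#' A connectome is a weighted, directed, region-by-region coupling matrix.
#' Entry `weights[i, j]` is the coupling strength from region `j` onto
#' region `i` (arbitrary connectome units). The diagonal is structurally
#' zero (no self-coupling) and all weights are nonnegative.
#'
#' @param weights square numeric matrix of nonnegative couplings with a
#'   zero diagonal; `weights[i, j]` couples region `j` to region `i`.
#' @param labels character vector of unique region names, one per row.
#' @param hemisphere optional per-region tag, one of `"left"`, `"right"`,
#'   `"none"`. Defaults to `"none"` for every region.
#' @param stroke_region optional region index or label designating the
#'   infarct core used by [apply_stroke()] and [apply_rebound()].
#' @return An object of class `connectome`: a list with elements
#'   `weights`, `labels`, `hemisphere` and `stroke_region` (integer index
#'   or `NA`).
#' @seealso [load_connectome()], [generate_synthetic_connectome()]
#' @export
connectome <- function(weights, labels = NULL, hemisphere = NULL,
                       stroke_region = NULL) {
  weights <- as.matrix(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(weights)))
  }
  if (is.null(hemisphere)) hemisphere <- rep("none", length(labels))
  sr <- resolve_region(stroke_region, labels)
  obj <- structure(
    list(weights = unname(weights), labels = as.character(labels),
         hemisphere = as.character(hemisphere), stroke_region = sr),
    class = "connectome")
  validate_connectome(obj)
}

resolve_region <- function(region, labels) {
  if (is.null(region) || (length(region) == 1L && is.na(region))) return(NA_integer_)
  if (is.character(region)) {
    idx <- match(region, labels)
    if (is.na(idx)) stop("unknown region label: ", region, call. = FALSE)
    return(idx)
  }
  idx <- as.integer(region)
  if (idx < 1L || idx > length(labels))
    stop("stroke_region index out of range: ", region, call. = FALSE)
  idx
}

validate_connectome <- function(x) {
  w <- x$weights
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("connectome weights must be a square matrix (got ",
         nrow(w), "x", ncol(w), ")", call. = FALSE)
  if (anyNA(w) || !is.numeric(w))
    stop("connectome weights must be numeric and free of NA", call. = FALSE)
  if (any(w < 0)) {
    bad <- which(w < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative weight at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (any(diag(w) != 0)) {
    bad <- which(diag(w) != 0)[1L]
    stop(sprintf("nonzero diagonal at region %d (self-coupling forbidden)", bad),
         call. = FALSE)
  }
  if (length(x$labels) != nrow(w))
    stop("number of labels (", length(x$labels),
         ") does not match matrix dimension (", nrow(w), ")", call. = FALSE)
  if (anyDuplicated(x$labels))
    stop("region labels must be unique", call. = FALSE)
  if (length(x$hemisphere) != nrow(w))
    stop("hemisphere tags must match matrix dimension", call. = FALSE)
  x
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<connectome> %d regions, %d directed links, total weight %.4g\n",
              n, sum(x$weights > 0), sum(x$weights)))
  if (!is.na(x$stroke_region))
    cat("  stroke region:", x$labels[x$stroke_region], "\n")
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$weights)

#' Read a connectome from a delimited matrix file
#'
#' Expects a comma-delimited square numeric matrix with a header row of
#' region labels; row order must equal column order. An optional sidecar
#' `<name>.meta.json` next to the file may carry `hemisphere` tags and the
#' `stroke_region` label.
#'
#' @param path path to the CSV matrix.
#' @return A validated [connectome()].
#' @export
load_connectome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- colnames(df)
  w <- as.matrix(df)
  if (!is.numeric(w)) {
    bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
    stop("non-numeric entries in column ", bad, " ('", labels[bad], "')",
         call. = FALSE)
  }
  if (nrow(w) != ncol(w))
    stop("matrix is not square: ", nrow(w), " rows x ", ncol(w), " columns",
         call. = FALSE)
  hemisphere <- NULL
  stroke_region <- NULL
  meta_path <- paste0(sub("\\.csv$", "", path), ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$hemisphere)) hemisphere <- meta$hemisphere
    if (!is.null(meta$stroke_region)) stroke_region <- meta$stroke_region
    if (!is.null(meta$labels) && !identical(as.character(meta$labels), labels))
      stop("sidecar labels disagree with CSV header", call. = FALSE)
  }
  connectome(w, labels, hemisphere, stroke_region)
}

#' Write a connectome to a delimited matrix file
#'
#' Writes the weight matrix as CSV (header = labels) plus a
#' `<name>.meta.json` sidecar with labels, hemisphere tags and the stroke
#' region. [load_connectome()] restores the object to full precision.
#'
#' @param conn a [connectome()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  w <- conn$weights
  colnames(w) <- conn$labels
  utils::write.table(format(w, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(labels = conn$labels, hemisphere = conn$hemisphere,
               stroke_region = if (is.na(conn$stroke_region)) NULL else
                 conn$labels[conn$stroke_region])
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Generate a synthetic connectome
#'
#' Stands in for an atlas-derived structural connectome. Off-diagonal
#' entries are selected independently with probability `density` and given
#' log-normal weights, the heavy-tailed form typical of tract-tracing
#' connectomes. The designated stroke region is built as a hub: it is
#' connected bidirectionally to every other region, with weights centred
#' at `hub_boost` times the median link weight, so that lesioning it has
#' a measurable network-wide effect on functional connectivity.
#'
#' @param n_regions number of regions (at least 3).
#' @param density probability in (0, 1] that an ordered off-diagonal pair
#'   is connected.
#' @param symmetric if `TRUE`, the matrix equals its transpose.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param meanlog,sdlog parameters of the log-normal weight distribution.
#' @param hub_boost median weight of the stroke region's links, as a
#'   multiple of the overall median link weight.
#' @param weight_scale overall multiplier of all weights; sets the
#'   network's working point relative to a fixed global coupling.
#' @param stroke_region index of the designated stroke region (labelled
#'   `"rM1"`).
#' @return A [connectome()].
#' @export
generate_synthetic_connectome <- function(n_regions, density = 0.3,
                                          symmetric = FALSE, seed = 1L,
                                          meanlog = 0, sdlog = 1,
                                          hub_boost = 2.5,
                                          weight_scale = 1,
                                          stroke_region = 1L) {
  if (n_regions < 3L) stop("n_regions must be at least 3", call. = FALSE)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(n_regions)
  k <- as.integer(stroke_region)
  w <- matrix(0, n, n)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  vals <- matrix(stats::rlnorm(n * n, meanlog, sdlog), n, n)
  w[mask] <- vals[mask]
  if (symmetric) {
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  diag(w) <- 0
  if (sum(w) == 0)
    stop("generated graph is empty; increase density or n_regions",
         call. = FALSE)
  # hub construction: the infarct target connects to every other region
  hub_mu <- log(hub_boost * stats::median(w[w > 0]))
  if (symmetric) {
    hub <- stats::rlnorm(n - 1L, hub_mu, sdlog / 2)
    w[-k, k] <- hub
    w[k, -k] <- hub
  } else {
    w[-k, k] <- stats::rlnorm(n - 1L, hub_mu, sdlog / 2)
    w[k, -k] <- stats::rlnorm(n - 1L, hub_mu, sdlog / 2)
  }
  w <- w * weight_scale
  labels <- sprintf("R%02d", seq_len(n))
  labels[k] <- "rM1"
  hemisphere <- rep(c("right", "left"), length.out = n)
  connectome(w, labels, hemisphere, stroke_region = k)
}

#' Specify a lesion
#'
#' Captures the two structural parameters of the stroke/recovery model:
#' the fraction `retain` of each link weight that survives on the stroke
#' region's connections (`retain = 0` is complete disconnection,
#' `retain = 0.9` means 10% damage) and the rebound factor `rebound`,
#' the multiple of the lost weight that is redistributed during recovery
#' (0 = no rewiring, up to 5 = five-fold over-compensation).
#'
#' @param stroke_region region index or label; if `NULL` the connectome's
#'   own `stroke_region` is used.
#' @param retain survival fraction `s` in \[0, 1\].
#' @param rebound rebound factor `r` in \[0, 5\].
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(stroke_region = NULL, retain = 1, rebound = 0) {
  if (retain < 0 || retain > 1)
    stop("retain must be in [0, 1]", call. = FALSE)
  if (rebound < 0 || rebound > 5)
    stop("rebound must be in [0, 5]", call. = FALSE)
  structure(list(stroke_region = stroke_region, retain = retain,
                 rebound = rebound),
            class = "lesion_spec")
}

lesion_region_index <- function(conn, spec) {
  sr <- spec$stroke_region
  if (is.null(sr)) {
    if (is.na(conn$stroke_region))
      stop("no stroke region: neither the lesion spec nor the connectome names one",
           call. = FALSE)
    return(conn$stroke_region)
  }
  resolve_region(sr, conn$labels)
}

#' Apply a stroke lesion to a connectome
#'
#' Damages the stroke region's links homogeneously: every weight on its
#' row and/or column is multiplied by the survival fraction
#' `spec$retain`. All weights between non-stroke regions are untouched and
#' the input connectome is not modified.
#'
#' @param conn a [connectome()].
#' @param spec a [lesion_spec()].
#' @param direction which links of the stroke region to damage. The
#'   default `"both"` scales afferent and efferent links (total
#'   disconnection at `retain = 0`); `"afferent"`/`"efferent"` scale only
#'   the incoming row or outgoing column.
#' @return A new [connectome()] with the lesion applied.
#' @export
apply_stroke <- function(conn, spec, direction = c("both", "afferent", "efferent")) {
  direction <- match.arg(direction)
  k <- lesion_region_index(conn, spec)
  s <- spec$retain
  w <- conn$weights
  if (direction %in% c("both", "afferent")) w[k, ] <- w[k, ] * s
  if (direction %in% c("both", "efferent")) w[, k] <- w[, k] * s
  out <- conn
  out$weights <- w
  out$stroke_region <- k
  out
}

#' Apply stroke plus rebound rewiring
#'
#' Starting from the lesioned connectome ([apply_stroke()]), a total
#' weight budget `B = rebound * (weight lost to the lesion)` is added back
#' to the network, modelling post-stroke structural rewiring. In the
#' default `"redistribute"` mode the budget is allocated across the nodes
#' that had a nonzero link to the stroke region in the healthy connectome,
#' proportionally to that healthy link strength; within each such node its
#' share is spread over its remaining non-stroke links proportionally to
#' their current weights, so no new links are created. In `"restore"` mode
#' the budget instead rebuilds the stroke region's own links,
#' proportionally to their healthy weights.
#'
#' The operator conserves the budget exactly:
#' `sum(output) - sum(lesioned) = B`.
#'
#' @param healthy the pre-stroke [connectome()].
#' @param spec a [lesion_spec()] with both `retain` and `rebound` set.
#' @param mode `"redistribute"` (default) or `"restore"`; see Details.
#' @param direction passed to [apply_stroke()].
#' @return A new [connectome()] with lesion and rebound applied.
#' @export
apply_rebound <- function(healthy, spec, mode = c("redistribute", "restore"),
                          direction = "both") {
  mode <- match.arg(mode)
  k <- lesion_region_index(healthy, spec)
  les <- apply_stroke(healthy, spec, direction = direction)
  r <- spec$rebound
  if (r == 0) return(les)
  hw <- healthy$weights
  if (all(hw[k, ] == 0) && all(hw[, k] == 0))
    stop("rebound requested but no node was connected to the stroke region",
         call. = FALSE)
  lost <- sum(healthy$weights) - sum(les$weights)
  budget <- r * lost
  if (budget == 0) return(les)
  w <- les$weights
  n <- nrow(w)
  if (mode == "restore") {
    stroke_total <- sum(hw[k, ]) + sum(hw[, k])
    w[k, ] <- w[k, ] + budget * hw[k, ] / stroke_total
    w[, k] <- w[, k] + budget * hw[, k] / stroke_total
  } else {
    strength <- hw[, k] + hw[k, ]       # healthy link to/from the infarct
    strength[k] <- 0
    donors <- which(strength > 0)
    # a donor whose only links were to the stroke region cannot receive
    capacity <- vapply(donors, function(i) {
      sum(w[i, -k]) + sum(w[-k, i])
    }, numeric(1L))
    keep <- capacity > 0
    donors <- donors[keep]
    capacity <- capacity[keep]
    if (length(donors) == 0L)
      stop("rebound requested but every connected node lost all other links",
           call. = FALSE)
    share <- budget * strength[donors] / sum(strength[donors])
    # additions are computed against the lesioned matrix, not cumulatively,
    # so that each donor contributes exactly its share even on shared links
    delta <- matrix(0, n, n)
    idx <- setdiff(seq_len(n), k)
    for (d in seq_along(donors)) {
      i <- donors[d]
      scale <- share[d] / capacity[d]
      delta[i, idx] <- delta[i, idx] + scale * w[i, idx]
      delta[idx, i] <- delta[idx, i] + scale * w[idx, i]
    }
    w <- w + delta
  }
  out <- les
  out$weights <- w
  out
}
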