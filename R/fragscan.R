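# Aggregation of sliding-window fragment docking scores into per-residue
# affinity profiles, core-binding-region calling, and pose-to-binding-site
# classification. The docking engine itself is an external, pluggable
# backend; only its invocation contract and score aggregation live here.

#' Attach docking scores to a fragment set
#'
#' @param fragments A \code{\link{make_fragments}} result (or a data.frame
#'   with \code{fragment_id}, \code{start_number}, \code{sequence}).
#' @param score_kcal_mol One score per fragment (kcal/mol; more negative =
#'   more favorable).
#' @return Data frame of class \code{"fragment_scores"}.
#' @export
fragment_scores <- function(fragments, score_kcal_mol) {
  d <- as.data.frame(fragments)
  if (!all(c("fragment_id", "start_number", "sequence") %in% names(d)))
    stop("fragments need columns fragment_id, start_number, sequence")
  score_kcal_mol <- as.numeric(score_kcal_mol)
  if (length(score_kcal_mol) != nrow(d))
    stop("need one score per fragment")
  if (any(!is.finite(score_kcal_mol))) stop("scores must be finite")
  d$score_kcal_mol <- score_kcal_mol
  attr(d, "parent") <- attr(fragments, "parent")
  class(d) <- c("fragment_scores", "data.frame")
  d
}

#' Per-residue affinity profile from fragment docking scores
#'
#' The binding score assigned to each residue is the arithmetic mean of the
#' scores of all fragments that contain that residue. Residues near the chain
#' termini are covered by fewer fragments and therefore averaged over fewer
#' docking runs; they are flagged as less accurate.
#'
#' @param scores A \code{\link{fragment_scores}} data frame.
#' @param parent The parent \code{\link{peptide_sequence}} (defaults to the
#'   one attached to \code{scores}).
#' @return Object of class \code{"residue_affinity_profile"}: data.frame with
#'   \code{residue_number}, \code{mean_score}, \code{n_fragments},
#'   \code{terminal_flag}.
#' @export
aggregate_per_residue <- function(scores, parent = attr(scores, "parent")) {
  d <- as.data.frame(scores)
  if (is.null(parent)) stop("no parent sequence supplied")
  stopifnot(inherits(parent, "peptide_sequence"))
  p_start <- parent$start_number
  p_end <- p_start + nchar(parent$residues) - 1L
  # every fragment must be the stated window of the parent
  for (i in seq_len(nrow(d))) {
    off <- d$start_number[i] - p_start
    w <- nchar(d$sequence[i])
    if (off < 0 || off + w > nchar(parent$residues) ||
        substring(parent$residues, off + 1L, off + w) != d$sequence[i])
      stop(sprintf("fragment %s (start %d) is not a window of the parent",
                   d$sequence[i], d$start_number[i]))
  }
  res_no <- seq.int(min(d$start_number),
                    max(d$start_number + nchar(d$sequence) - 1L))
  mean_score <- n_frag <- numeric(length(res_no))
  for (j in seq_along(res_no)) {
    r <- res_no[j]
    covers <- d$start_number <= r &
      (d$start_number + nchar(d$sequence) - 1L) >= r
    n_frag[j] <- sum(covers)
    mean_score[j] <- mean(d$score_kcal_mol[covers])
  }
  out <- data.frame(residue_number = res_no, mean_score = mean_score,
                    n_fragments = as.integer(n_frag),
                    terminal_flag = n_frag < max(n_frag))
  attr(out, "parent") <- parent
  class(out) <- c("residue_affinity_profile", "data.frame")
  out
}

#' Call the core binding region of a residue affinity profile
#'
#' Locates the global minimum of the per-residue mean scores and extends it to
#' the maximal contiguous run of residues whose score is within \code{margin}
#' of that minimum. If other disjoint runs also fall within the margin, the
#' run containing the global minimum is returned with a warning.
#'
#' @param profile A \code{\link{aggregate_per_residue}} result with at least
#'   7 residues.
#' @param margin Score margin (kcal/mol) for extending the region around the
#'   minimum; default 0.5.
#' @return List with \code{start}, \code{end} (parent residue numbers),
#'   \code{core_score} (the minimum mean score), \code{degenerate} (TRUE for a
#'   flat profile) and \code{clipped} (TRUE when the region touches a
#'   terminus, where coverage is thin).
#' @export
call_core_region <- function(profile, margin = 0.5) {
  stopifnot(inherits(profile, "residue_affinity_profile"))
  s <- profile$mean_score
  if (length(s) < 7L) stop("profile must cover at least 7 residues")
  degenerate <- diff(range(s)) < .Machine$double.eps^0.5
  if (degenerate)
    warning("flat affinity profile: core region call is degenerate")
  i_min <- which.min(s)
  within <- s <= s[i_min] + margin
  # contiguous run containing the global minimum
  runs <- rle(within)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_id <- findInterval(i_min, starts)
  lo <- starts[run_id]; hi <- ends[run_id]
  if (sum(runs$values) > 1L && !degenerate)
    warning("multiple disjoint regions within margin; returning the one containing the global minimum")
  clipped <- lo == 1L || hi == length(s)
  if (clipped && !degenerate &&
      any(profile$terminal_flag[c(lo, hi)]))
    message("core region touches a chain terminus, where fragment coverage is thin")
  list(start = profile$residue_number[lo],
       end = profile$residue_number[hi],
       core_score = s[i_min], degenerate = degenerate, clipped = clipped)
}

#' Classify a docking pose against reference binding-site ligands
#'
#' Computes the minimum backbone-backbone distance between a pose and
#' reference crystallographic NLS ligand coordinates marking the major (and
#' optionally minor) binding site; the pose is assigned to the closest
#' reference within \code{cutoff}.
#'
#' @param pose_coords Numeric matrix (n x 3) of pose backbone coordinates.
#' @param major_ref Matrix of backbone coordinates of the major-site
#'   reference ligand (same frame), or NULL.
#' @param minor_ref Optional matrix for the minor site.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @return List with \code{site} ("major", "minor" or "other") and
#'   \code{distance} (minimum distance to the assigned/nearest reference, Å).
#' @export
classify_pose_site <- function(pose_coords, major_ref = NULL,
                               minor_ref = NULL, cutoff = 5) {
  pose_coords <- as.matrix(pose_coords)
  if (!nrow(pose_coords) || ncol(pose_coords) != 3L)
    stop("'pose_coords' must be a non-empty n x 3 matrix")
  if (is.null(major_ref)) {
    warning("no major-site reference supplied; classifying as 'other'")
    return(list(site = "other", distance = NA_real_))
  }
  min_dist <- function(a, b) {
    b <- as.matrix(b)
    dmin <- Inf
    for (i in seq_len(nrow(a))) {
      d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
        (b[, 3] - a[i, 3])^2
      dmin <- min(dmin, min(d2))
    }
    sqrt(dmin)
  }
  d_major <- min_dist(pose_coords, major_ref)
  d_minor <- if (is.null(minor_ref)) Inf else min_dist(pose_coords, minor_ref)
  if (d_major <= cutoff && d_major <= d_minor)
    list(site = "major", distance = d_major)
  else if (d_minor <= cutoff)
    list(site = "minor", distance = d_minor)
  else
    list(site = "other", distance = min(d_major, d_minor))
}

#' Docking backend configuration
#'
#' @param box_size Search box dimensions in Angstrom (default 50 x 90 x 90,
#'   enclosing the whole receptor).
#' @param box_center Box center coordinates (defaults to the receptor
#'   centroid at run time).
#' @param exhaustiveness_multiplier Search-effort multiplier over the engine
#'   default (default 32).
#' @param receptor Path to the receptor structure (PDB).
#' @return Object of class \code{"docking_config"}.
#' @export
docking_config <- function(box_size = c(50, 90, 90), box_center = NULL,
                           exhaustiveness_multiplier = 32, receptor = NULL) {
  if (any(box_size <= 0)) stop("box dimensions must be positive")
  structure(list(box_size = box_size, box_center = box_center,
                 exhaustiveness_multiplier = exhaustiveness_multiplier,
                 receptor = receptor),
            class = "docking_config")
}

#' Run a docking backend over a fragment set
#'
#' Invokes a pluggable docking engine once per fragment over the whole-
#' receptor search box and harvests the best score per fragment. Results are
#' cached to CSV: if the cache exists the backend is not invoked again. The
#' default backend requires an external docking engine on the host and is
#' never exercised by the test suite; tests supply a mock backend.
#'
#' @param fragments A \code{\link{make_fragments}} result.
#' @param config A \code{\link{docking_config}}.
#' @param backend Function \code{(fragment_row, config) -> list(score = ...)};
#'   if NULL an external engine is required on the PATH.
#' @param cache_path Optional CSV path for caching scores.
#' @return A \code{\link{fragment_scores}} data frame.
#' @export
run_backend <- function(fragments, config, backend = NULL,
                        cache_path = NULL) {
  stopifnot(inherits(config, "docking_config"))
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cached <- utils::read.csv(cache_path, stringsAsFactors = FALSE)
    return(fragment_scores(fragments, cached$score_kcal_mol))
  }
  if (is.null(backend)) {
    if (Sys.which("vina") == "")
      stop("no docking backend: supply 'backend' or install AutoDock Vina on the PATH")
    stop("external engine invocation requires receptor/fragment structure preparation; supply a 'backend' function wrapping your engine")
  }
  d <- as.data.frame(fragments)
  scores <- vapply(seq_len(nrow(d)), function(i) {
    out <- backend(d[i, ], config)
    as.numeric(out$score)
  }, numeric(1))
  res <- fragment_scores(fragments, scores)
  if (!is.null(cache_path))
    utils::write.csv(as.data.frame(res), cache_path, row.names = FALSE)
  res
}
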