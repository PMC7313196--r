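# plain density clustering (DBSCAN-style, Euclidean, O(n^2)): scaffold sets
# at desk scale are hundreds of points, so no spatial index is needed
density_cluster <- function(x, eps, min_pts) {
  n <- nrow(x)
  if (n == 0L) return(integer())
  d <- as.matrix(stats::dist(x))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neighbors) >= min_pts
  labels <- integer(n)  # 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (nb in neighbors[[j]]) {
        if (labels[nb] == 0L) {
          labels[nb] <- cl
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

# binning feature space: GC, log10 coverage, top TNF principal components.
# Each axis is divided by a fixed physical scale (not a data-driven sd, which
# would inflate uninformative axes into pure noise dimensions): one unit of
# distance means "one tolerance" on that axis, so eps is interpretable.
binning_features <- function(profiles, n_pc = 3, gc_scale = 5,
                             cov_scale = 0.5, tnf_scale = 0.05) {
  tnf <- do.call(rbind, profiles$tnf)
  n_pc <- min(n_pc, ncol(tnf), nrow(tnf) - 1L)
  pcs <- if (n_pc >= 1 && nrow(tnf) > 1) {
    prcomp(tnf, center = TRUE, scale. = FALSE)$x[, seq_len(n_pc), drop = FALSE]
  } else {
    matrix(0, nrow(tnf), 1)
  }
  cbind(
    gc = profiles$gc_percent / gc_scale,
    logcov = log10(pmax(profiles$coverage, 1e-3)) / cov_scale,
    pcs / tnf_scale
  )
}

#' Preliminary scaffold binning
#'
#' Scaffolds are first grouped by their phylum/class-level taxonomy label;
#' within each label group they are clustered by density on standardized
#' (GC, log10 coverage, top-3 TNF principal components). Labeled scaffolds
#' falling out as density noise join the nearest cluster sharing their label
#' (taxonomy is treated as strong evidence); unlabeled scaffolds are
#' assigned to the nearest cluster centroid within distance `eps`, or left
#' unbinned. Each bin carries its majority label.
#'
#' Feature axes are divided by fixed scales (`gc_scale` percentage points,
#' `cov_scale` log10 units, `tnf_scale` TNF Euclidean units) so one unit of
#' clustering distance corresponds to one tolerance on each axis; `eps` is
#' expressed in those units.
#'
#' @param profiles A [profile_scaffolds()] table.
#' @param eps Density clustering radius in scaled feature units.
#' @param min_pts Minimum neighborhood size for a core point.
#' @param gc_scale,cov_scale,tnf_scale Per-axis scales defining one unit of
#'   clustering distance.
#' @return A `bin_set` object: list with `bins` (per-bin summary tibble) and
#'   `membership` (`bin_id`, `scaffold_id`).
#' @export
preliminary_bins <- function(profiles, eps = 1.0, min_pts = 3, gc_scale = 5,
                             cov_scale = 0.5, tnf_scale = 0.05) {
  if (!nrow(profiles)) abort("profiles table is empty")
  x <- binning_features(profiles, gc_scale = gc_scale, cov_scale = cov_scale,
                        tnf_scale = tnf_scale)
  lab <- profiles$taxonomy_label
  if (all(is.na(lab))) {
    warn("all scaffolds unlabeled: falling back to pure density clustering")
  }
  cluster_id <- rep(NA_integer_, nrow(profiles))
  next_cl <- 0L
  for (g in unique(lab[!is.na(lab)])) {
    rows <- which(!is.na(lab) & lab == g)
    cl <- density_cluster(x[rows, , drop = FALSE], eps, min_pts)
    if (all(cl == 0L)) cl <- rep(1L, length(cl))  # tiny group: keep together
    # attach labeled noise points to the nearest same-label cluster
    if (any(cl == 0L)) {
      cents <- centroids(x[rows, , drop = FALSE], cl)
      for (i in which(cl == 0L)) {
        dd <- sqrt(colSums((t(cents) - x[rows[i], ])^2))
        cl[i] <- as.integer(rownames(cents)[which.min(dd)])
      }
    }
    cluster_id[rows] <- cl + next_cl
    next_cl <- next_cl + max(cl)
  }
  # unlabeled scaffolds: nearest existing centroid within eps, else unbinned
  un <- which(is.na(lab))
  if (length(un)) {
    if (any(!is.na(cluster_id))) {
      cents <- centroids(x, cluster_id)
      for (i in un) {
        dd <- sqrt(colSums((t(cents) - x[i, ])^2))
        if (min(dd) <= eps) {
          cluster_id[i] <- as.integer(rownames(cents)[which.min(dd)])
        }
      }
    } else {
      cl <- density_cluster(x[un, , drop = FALSE], eps, min_pts)
      cluster_id[un] <- ifelse(cl == 0L, NA_integer_, cl)
    }
  }
  build_bin_set(profiles, cluster_id, status = "preliminary")
}

centroids <- function(x, cl) {
  keep <- !is.na(cl) & cl != 0L
  agg <- rowsum(x[keep, , drop = FALSE], cl[keep])
  agg / as.vector(table(cl[keep])[rownames(agg)])
}

build_bin_set <- function(profiles, cluster_id, status) {
  binned <- !is.na(cluster_id)
  membership <- tibble(
    cluster = cluster_id[binned],
    scaffold_id = profiles$scaffold_id[binned]
  )
  stats <- profiles[binned, ] |>
    mutate(cluster = cluster_id[binned]) |>
    group_by(.data$cluster) |>
    summarise(
      n_scaffolds = n(),
      total_length = sum(.data$length),
      gc_mean = sum(.data$gc_percent * .data$length) / sum(.data$length),
      gc_sd = sd(.data$gc_percent),
      coverage_median = median(.data$coverage),
      taxonomy_label = majority_label(.data$taxonomy_label),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$total_length))
  stats$bin_id <- sprintf("bin%02d", seq_len(nrow(stats)))
  membership$bin_id <- stats$bin_id[match(membership$cluster, stats$cluster)]
  structure(list(
    bins = select(stats, "bin_id", "taxonomy_label", "n_scaffolds",
                  "total_length", "gc_mean", "gc_sd", "coverage_median") |>
      mutate(status = status),
    membership = select(membership, "bin_id", "scaffold_id")
  ), class = "bin_set")
}

majority_label <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

#' @export
print.bin_set <- function(x, ...) {
  cat("<bin_set> ", nrow(x$bins), " bins (",
      sum(x$bins$n_scaffolds), " scaffolds, status: ",
      paste(unique(x$bins$status), collapse = "/"), ")\n", sep = "")
  print(x$bins)
  invisible(x)
}

#' Quality-screen the scaffolds of each bin
#'
#' Re-applies the binning criteria per scaffold, plus the paired-read rule:
#' a scaffold is rejected when its paired fraction is not strictly greater
#' than `paired_min` (undefined paired fraction also rejects), when its GC
#' or log10 coverage deviates from the bin median beyond `gc_tol` /
#' `cov_tol`, when its TNF distance from the bin centroid exceeds
#' `tnf_factor` times the bin's median within-bin distance (a robust cutoff:
#' the median is insensitive to a minority of contaminant scaffolds, where
#' an upper quantile of the observed distances would be dragged up by the
#' very outliers it is meant to catch), or when its taxonomy label conflicts
#' with the bin majority. The first failing criterion (in that order) is
#' recorded as the reason.
#'
#' @param bins A `bin_set`.
#' @param profiles A [profile_scaffolds()] table covering all bin scaffolds.
#' @param paired_min Paired-fraction floor; pass requires `> paired_min`.
#' @param gc_tol GC tolerance around the bin median, percentage points.
#' @param cov_tol log10-coverage tolerance around the bin median.
#' @param tnf_factor Multiple of the median within-bin TNF centroid distance
#'   used as the composition-outlier cutoff.
#' @return A `screen_report` tibble: `bin_id`, `scaffold_id`, `accepted`,
#'   `reason` (`NA` when accepted).
#' @export
screen_scaffolds <- function(bins, profiles, paired_min = 0.90, gc_tol = 5,
                             cov_tol = 0.5, tnf_factor = 2) {
  stopifnot(inherits(bins, "bin_set"))
  missing <- setdiff(bins$membership$scaffold_id, profiles$scaffold_id)
  if (length(missing)) {
    abort(sprintf("profiles do not cover %d bin scaffold(s)", length(missing)))
  }
  prof <- inner_join(bins$membership, profiles, by = "scaffold_id")
  out <- prof |>
    group_by(.data$bin_id) |>
    dplyr::group_modify(function(d, key) {
      gc_med <- median(d$gc_percent)
      cov_med <- median(log10(pmax(d$coverage, 1e-3)))
      tnf <- do.call(rbind, d$tnf)
      cent <- colMeans(tnf)
      tnf_d <- sqrt(rowSums((tnf - rep(cent, each = nrow(tnf)))^2))
      tnf_cut <- tnf_factor * median(tnf_d)
      maj <- majority_label(d$taxonomy_label)
      reason <- rep(NA_character_, nrow(d))
      fail_tax <- !is.na(d$taxonomy_label) & !is.na(maj) &
        d$taxonomy_label != maj
      reason[fail_tax] <- "taxonomy_conflict"
      reason[tnf_d > tnf_cut] <- "composition_outlier"
      fail_cov <- abs(log10(pmax(d$coverage, 1e-3)) - cov_med) > cov_tol
      reason[fail_cov] <- "coverage_outlier"
      reason[abs(d$gc_percent - gc_med) > gc_tol] <- "gc_outlier"
      fail_pf <- is.na(d$paired_fraction) | d$paired_fraction <= paired_min
      reason[fail_pf] <- "paired_fraction"
      tibble(scaffold_id = d$scaffold_id,
             accepted = is.na(reason), reason = reason)
    }) |>
    ungroup()
  structure(out, class = c("screen_report", class(out)))
}

#' Iterative bin refinement
#'
#' Alternates the quality screen with bin-statistic recomputation until no
#' scaffold is rejected or `max_rounds` is reached (the external
#' re-assembly step between rounds is the user's job; scaffolds pass
#' through unchanged here). The accepted set never grows between rounds.
#' Bins emptied by screening are dropped with a warning.
#'
#' @inheritParams screen_scaffolds
#' @param max_rounds Maximum screening rounds (>= 1).
#' @param ... Passed to [screen_scaffolds()].
#' @return A `bin_set` with status `"screened"` and an attribute
#'   `screen_log` (per-round `screen_report`s).
#' @export
refine_bins <- function(bins, profiles, max_rounds = 3, ...) {
  stopifnot(max_rounds >= 1)
  log <- list()
  for (round in seq_len(max_rounds)) {
    rep <- screen_scaffolds(bins, profiles, ...)
    log[[round]] <- mutate(rep, round = round)
    if (all(rep$accepted)) break
    keep <- rep$scaffold_id[rep$accepted]
    membership <- filter(bins$membership, .data$scaffold_id %in% keep)
    emptied <- setdiff(bins$bins$bin_id, membership$bin_id)
    if (length(emptied)) {
      warn(sprintf("bin(s) emptied by screening and dropped: %s",
                   paste(emptied, collapse = ", ")))
    }
    if (!nrow(membership)) abort("screening rejected every scaffold")
    bins <- rebuild_bins(membership, profiles)
  }
  bins$bins$status <- "screened"
  attr(bins, "screen_log") <- bind_rows(log)
  bins
}

# recompute bin statistics for fixed membership, preserving bin ids
rebuild_bins <- function(membership, profiles) {
  stats <- inner_join(membership, profiles, by = "scaffold_id") |>
    group_by(.data$bin_id) |>
    summarise(
      n_scaffolds = n(),
      total_length = sum(.data$length),
      gc_mean = sum(.data$gc_percent * .data$length) / sum(.data$length),
      gc_sd = sd(.data$gc_percent),
      coverage_median = median(.data$coverage),
      taxonomy_label = majority_label(.data$taxonomy_label),
      .groups = "drop"
    ) |>
    mutate(status = "preliminary") |>
    select("bin_id", "taxonomy_label", "n_scaffolds", "total_length",
           "gc_mean", "gc_sd", "coverage_median", "status") |>
    arrange(.data$bin_id)
  structure(list(bins = stats, membership = membership), class = "bin_set")
}

#' Simplified marker-based completeness and contamination
#'
#' `completeness = 100 * (families present at least once) / |marker set|`;
#' `contamination = 100 * sum(max(0, copies - 1)) / |marker set|`. This is a
#' simplified single-copy marker tally: marker collocation and
#' lineage-specific set corrections are deliberately out of scope.
#'
#' @param bins A `bin_set`.
#' @param marker_annotations Tibble (`scaffold_id`, `family`): observed
#'   marker-family hits per scaffold.
#' @param marker_set Character vector of all expected family ids.
#' @return Tibble (`bin_id`, `completeness`, `contamination`,
#'   `n_families_present`, `n_extra_copies`).
#' @export
marker_qc <- function(bins, marker_annotations, marker_set) {
  stopifnot(inherits(bins, "bin_set"), length(marker_set) > 0)
  unknown <- setdiff(marker_annotations$family, marker_set)
  if (length(unknown)) {
    abort(sprintf("annotation names unknown marker family: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  ann <- inner_join(bins$membership, marker_annotations,
                    by = "scaffold_id", relationship = "many-to-many")
  purrr::map_dfr(bins$bins$bin_id, function(b) {
    copies <- table(factor(ann$family[ann$bin_id == b], levels = marker_set))
    tibble(
      bin_id = b,
      completeness = 100 * sum(copies >= 1) / length(marker_set),
      contamination = 100 * sum(pmax(copies - 1, 0)) / length(marker_set),
      n_families_present = sum(copies >= 1),
      n_extra_copies = sum(pmax(copies - 1, 0))
    )
  })
}

#' Table-1-style bin report
#'
#' One row per bin: total length, percent GC, scaffold count, optional
#' completeness/contamination (simplified marker tally) and taxonomy.
#'
#' @param bins A `bin_set`.
#' @param qc Optional [marker_qc()] table.
#' @return Tibble.
#' @export
bin_summary <- function(bins, qc = NULL) {
  out <- bins$bins |>
    select("bin_id", "total_length", pct_gc = "gc_mean",
           n_scaffolds = "n_scaffolds", coverage_median = "coverage_median",
           taxonomy = "taxonomy_label", "status")
  if (!is.null(qc)) {
    out <- left_join(out, select(qc, "bin_id", "completeness", "contamination"),
                     by = "bin_id")
  }
  out
}

#' @method tidy bin_set
#' @export
tidy.bin_set <- function(x, ...) bin_summary(x, ...)

#' @method glance bin_set
#' @export
glance.bin_set <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins),
    n_scaffolds = sum(x$bins$n_scaffolds),
    total_length = sum(x$bins$total_length),
    status = paste(unique(x$bins$status), collapse = "/")
  )
}
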