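PIPELINE_STAGES <- c("simulate", "profile", "bin", "refine", "qc", "rank",
                     "abundance")

#' Configure an end-to-end pipeline run
#'
#' Bundles and validates every stage's parameters. All randomness flows from
#' the community seed; generator stages derive their own seeds from it by a
#' fixed per-stage offset, so each stage is independently reproducible. The
#' configuration round-trips losslessly through YAML.
#'
#' @param community A [community_config()].
#' @param min_scaffold_len,mean_scaffold_len Fragmentation / profiling
#'   lengths, bases.
#' @param map_k Seed length for the read mapper.
#' @param map_min_identity Identity floor (percent) for the profiling
#'   mapping (tolerant of sequencing error).
#' @param recruit_min_identity Identity floor for abundance read
#'   recruitment (100 = exact).
#' @param eps,min_pts Density clustering parameters (standardized feature
#'   units / points).
#' @param paired_min,gc_tol,cov_tol,tnf_factor Screening thresholds, see
#'   [screen_scaffolds()].
#' @param max_rounds Refinement rounds.
#' @param amplicon_region,amplicon_n_reads Amplicon simulation, see
#'   [simulate_amplicons()].
#' @param asv_min_identity ASV-to-MAG identity floor, percent.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(community = community_config(),
                            min_scaffold_len = 10000,
                            mean_scaffold_len = 20000,
                            map_k = 16,
                            map_min_identity = 97,
                            recruit_min_identity = 100,
                            eps = 1.0, min_pts = 3,
                            paired_min = 0.90, gc_tol = 5, cov_tol = 0.5,
                            tnf_factor = 2, max_rounds = 3,
                            amplicon_region = c(516, 925),
                            amplicon_n_reads = 20000,
                            asv_min_identity = 97) {
  stopifnot(inherits(community, "community_config"),
            min_scaffold_len > 0, mean_scaffold_len >= min_scaffold_len,
            map_k >= 11,
            map_min_identity > 0, map_min_identity <= 100,
            recruit_min_identity > 0, recruit_min_identity <= 100,
            eps > 0, min_pts >= 1, paired_min >= 0, paired_min <= 1,
            max_rounds >= 1, length(amplicon_region) == 2,
            amplicon_n_reads > 0,
            asv_min_identity > 0, asv_min_identity <= 100)
  structure(list(
    community = community,
    min_scaffold_len = as.integer(min_scaffold_len),
    mean_scaffold_len = as.integer(mean_scaffold_len),
    map_k = as.integer(map_k),
    map_min_identity = as.numeric(map_min_identity),
    recruit_min_identity = as.numeric(recruit_min_identity),
    eps = as.numeric(eps), min_pts = as.integer(min_pts),
    paired_min = as.numeric(paired_min), gc_tol = as.numeric(gc_tol),
    cov_tol = as.numeric(cov_tol), tnf_factor = as.numeric(tnf_factor),
    max_rounds = as.integer(max_rounds),
    amplicon_region = as.integer(amplicon_region),
    amplicon_n_reads = as.integer(amplicon_n_reads),
    asv_min_identity = as.numeric(asv_min_identity)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$community <- unclass(x$community)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cc <- do.call(community_config, x$community)
  do.call(pipeline_config, c(list(community = cc),
                             x[setdiff(names(x), "community")]))
}

#' Run the pipeline end to end
#'
#' Executes the stages in dependency order: `simulate` (community, reads,
#' amplicons, truth tables), `profile` (mapping + per-scaffold features),
#' `bin` (preliminary bins), `refine` (pair recruitment summary + quality
#' screen rounds), `qc` (marker tallies), `rank` (16S relatedness of
#' community members), `abundance` (read recruitment at the exact-identity
#' floor, amplicon matching, concordance). All artifacts are written to
#' `outdir` as FASTA/FASTQ/TSV; a manifest records each artifact's MD5
#' checksum, so two runs with the same configuration can be compared
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Stages to run (default all, in order). A stage whose
#'   upstream artifacts are neither in memory nor on disk raises an error
#'   naming the stage to run first.
#' @return A `pipeline_run` object: list with `manifest` (tibble: stage,
#'   artifact, path, md5), `state` (in-memory results), `config`.
#' @export
run_pipeline <- function(config, outdir, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  state <- list()
  manifest <- list()
  for (stage in PIPELINE_STAGES) {
    if (!stage %in% stages) next
    fn <- get(paste0("stage_", stage), mode = "function")
    res <- fn(config, outdir, state)
    state <- res$state
    if (length(res$artifacts)) {
      manifest[[stage]] <- tibble(
        stage = stage,
        artifact = names(res$artifacts),
        path = unname(res$artifacts),
        md5 = unname(tools::md5sum(unname(res$artifacts)))
      )
    }
  }
  manifest <- bind_rows(manifest)
  write_table_tsv(select(manifest, -"path"), file.path(outdir, "manifest.tsv"))
  structure(list(manifest = manifest, state = state, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", length(unique(x$manifest$stage)), " stages, ",
      nrow(x$manifest), " artifacts\n", sep = "")
  print(count(x$manifest, .data$stage))
  invisible(x)
}

need_artifact <- function(state, key, stage, needed_by) {
  if (!is.null(state[[key]])) return(state[[key]])
  abort(sprintf("stage '%s' requires outputs of stage '%s': run it first",
                needed_by, stage))
}

out_path <- function(outdir, name) file.path(outdir, name)

stage_simulate <- function(config, outdir, state) {
  truth <- generate_genomes(config$community)
  truth <- fragment_genomes(truth, min_len = config$min_scaffold_len,
                            mean_len = config$mean_scaffold_len)
  reads <- simulate_reads(truth)
  amplicons <- simulate_amplicons(truth, region = config$amplicon_region,
                                  n_reads = config$amplicon_n_reads)
  p <- c(
    scaffolds = out_path(outdir, "scaffolds.fasta"),
    r1 = out_path(outdir, "reads_R1.fastq"),
    r2 = out_path(outdir, "reads_R2.fastq"),
    scaffold_origin = out_path(outdir, "truth_scaffold_origin.tsv"),
    read_origin = out_path(outdir, "truth_read_origin.tsv"),
    true_abundance = out_path(outdir, "truth_abundance.tsv"),
    marker_loci = out_path(outdir, "truth_marker_loci.tsv"),
    ssu_loci = out_path(outdir, "truth_ssu_loci.tsv"),
    labels = out_path(outdir, "scaffold_labels.tsv"),
    asv_table = out_path(outdir, "asv_table.tsv")
  )
  write_fasta(tibble(id = truth$scaffolds$scaffold_id,
                     seq = truth$scaffolds$seq), p["scaffolds"])
  write_fastq(reads$r1, p["r1"])
  write_fastq(reads$r2, p["r2"])
  write_table_tsv(select(truth$scaffolds, -"seq"), p["scaffold_origin"])
  write_table_tsv(reads$read_origin, p["read_origin"])
  write_table_tsv(truth$true_abundance, p["true_abundance"])
  write_table_tsv(truth$marker_loci, p["marker_loci"])
  write_table_tsv(select(truth$ssu_loci, -"seq"), p["ssu_loci"])
  labels <- tibble(
    scaffold_id = truth$scaffolds$scaffold_id,
    taxonomy_label = truth$genomes$label[
      match(truth$scaffolds$genome_id, truth$genomes$genome_id)]
  ) |> filter(!is.na(.data$taxonomy_label))
  write_table_tsv(labels, p["labels"])
  write_table_tsv(amplicons, p["asv_table"])
  state$truth <- truth
  state$reads <- reads
  state$amplicons <- amplicons
  state$labels <- labels
  list(state = state, artifacts = p)
}

stage_profile <- function(config, outdir, state) {
  truth <- need_artifact(state, "truth", "simulate", "profile")
  reads <- need_artifact(state, "reads", "simulate", "profile")
  index <- build_read_index(
    tibble(id = truth$scaffolds$scaffold_id, seq = truth$scaffolds$seq),
    k = config$map_k)
  aln <- map_reads(reads, index, min_identity = config$map_min_identity)
  aln <- annotate_pair_status(aln)
  profiles <- profile_scaffolds(
    tibble(scaffold_id = truth$scaffolds$scaffold_id, seq = truth$scaffolds$seq),
    alignments = aln, labels = state$labels,
    min_len = config$min_scaffold_len)
  p <- c(alignments = out_path(outdir, "alignments.tsv"),
         profiles = out_path(outdir, "profiles.tsv"))
  write_table_tsv(aln, p["alignments"])
  write_table_tsv(select(profiles, -"tnf"), p["profiles"])
  state$index <- index
  state$alignments <- aln
  state$profiles <- profiles
  list(state = state, artifacts = p)
}

stage_bin <- function(config, outdir, state) {
  profiles <- need_artifact(state, "profiles", "profile", "bin")
  bins <- preliminary_bins(profiles, eps = config$eps,
                           min_pts = config$min_pts)
  p <- c(bins = out_path(outdir, "bins.tsv"),
         membership = out_path(outdir, "bin_membership.tsv"))
  write_table_tsv(bins$bins, p["bins"])
  write_table_tsv(bins$membership, p["membership"])
  state$bins <- bins
  list(state = state, artifacts = p)
}

stage_refine <- function(config, outdir, state) {
  bins <- need_artifact(state, "bins", "bin", "refine")
  profiles <- need_artifact(state, "profiles", "profile", "refine")
  aln <- need_artifact(state, "alignments", "profile", "refine")
  reads <- need_artifact(state, "reads", "simulate", "refine")
  recruit <- purrr::map_dfr(bins$bins$bin_id, function(b) {
    scf <- bins$membership$scaffold_id[bins$membership$bin_id == b]
    tidy(recruit_pairs(aln, scf, reads, bin_id = b))
  })
  screened <- refine_bins(bins, profiles, max_rounds = config$max_rounds,
                          paired_min = config$paired_min,
                          gc_tol = config$gc_tol, cov_tol = config$cov_tol,
                          tnf_factor = config$tnf_factor)
  p <- c(recruitment = out_path(outdir, "recruitment.tsv"),
         screen_report = out_path(outdir, "screen_report.tsv"),
         bins_screened = out_path(outdir, "bins_screened.tsv"),
         membership_screened = out_path(outdir, "bin_membership_screened.tsv"))
  write_table_tsv(recruit, p["recruitment"])
  write_table_tsv(attr(screened, "screen_log"), p["screen_report"])
  write_table_tsv(screened$bins, p["bins_screened"])
  write_table_tsv(screened$membership, p["membership_screened"])
  state$bins_screened <- screened
  list(state = state, artifacts = p)
}

stage_qc <- function(config, outdir, state) {
  truth <- need_artifact(state, "truth", "simulate", "qc")
  bins <- need_artifact(state, "bins_screened", "refine", "qc")
  ann <- select(truth$marker_loci, "scaffold_id", "family")
  marker_set <- sprintf("m%03d", seq_len(config$community$n_marker_families))
  qc <- marker_qc(bins, ann, marker_set)
  summary <- bin_summary(bins, qc)
  p <- c(qc = out_path(outdir, "marker_qc.tsv"),
         bin_summary = out_path(outdir, "bin_summary.tsv"))
  write_table_tsv(qc, p["qc"])
  write_table_tsv(summary, p["bin_summary"])
  state$qc <- qc
  list(state = state, artifacts = p)
}

stage_rank <- function(config, outdir, state) {
  truth <- need_artifact(state, "truth", "simulate", "rank")
  ssu <- truth$ssu_loci |> group_by(.data$genome_id) |> slice(1) |> ungroup()
  rel <- identity_matrix(ssu_seqs = setNames(ssu$seq, ssu$genome_id))
  p <- c(relatedness = out_path(outdir, "relatedness.tsv"))
  write_table_tsv(rel$pairs, p["relatedness"])
  state$relatedness <- rel
  list(state = state, artifacts = p)
}

stage_abundance <- function(config, outdir, state) {
  truth <- need_artifact(state, "truth", "simulate", "abundance")
  reads <- need_artifact(state, "reads", "simulate", "abundance")
  bins <- need_artifact(state, "bins_screened", "refine", "abundance")
  index <- need_artifact(state, "index", "profile", "abundance")
  amplicons <- need_artifact(state, "amplicons", "simulate", "abundance")
  aln100 <- map_reads(reads, index,
                      min_identity = config$recruit_min_identity)
  membership <- left_join(bins$membership, bins$bins[, c("bin_id", "taxonomy_label")],
                          by = "bin_id") |>
    mutate(taxon_group = dplyr::coalesce(.data$taxonomy_label, .data$bin_id))
  meta <- metagenomic_abundance(aln100, membership)
  gen <- filter(truth$genomes, !.data$is_host)
  ssu <- truth$ssu_loci |>
    mutate(label = gen$label[match(.data$genome_id, gen$genome_id)]) |>
    filter(!is.na(.data$label))
  amp <- amplicon_abundance(
    state$amplicons,
    tibble(id = paste0(ssu$genome_id, "_ssu", ssu$copy), seq = ssu$seq,
           taxon_group = ssu$label),
    min_identity = config$asv_min_identity)
  both <- bind_rows(meta, amp)
  comp <- compare_metrics(both)
  p <- c(abundance = out_path(outdir, "abundance.tsv"),
         concordance = out_path(outdir, "concordance.tsv"))
  write_table_tsv(both, p["abundance"])
  write_table_tsv(comp, p["concordance"])
  state$abundance <- both
  state$concordance <- comp
  list(state = state, artifacts = p)
}
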