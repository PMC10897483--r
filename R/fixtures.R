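# Frozen test bundles, regenerated from the simulator at pinned seeds.
# Fixtures are generated, never hand-edited; the manifest pins every
# generator parameter and the checksums of the emitted files.

fixture_specs <- function() {
  list(
    clean_wt = list(
      n_reads = 300L, seed = 211L, sub_error_rate = 0,
      class_mix = c(wildtype = 1)),
    # heterogeneous paired-nickase spectrum: 60% edited, 10% vector
    paired_nickase_mix = list(
      n_reads = 2000L, seed = 212L, sub_error_rate = 0.001,
      class_mix = c(wildtype = 0.40, nhej_indel = 0.08,
                    internick_deletion = 0.10, mmej_deletion = 0.17,
                    templated_insertion = 0.08, vector_insertion = 0.10,
                    combined = 0.07)),
    # nuclease spectrum: dominant perfect inter-cut deletion (59% of
    # edited reads) plus vector insertions at 9.8% of reads
    nuclease_mix = list(
      n_reads = 2000L, seed = 213L, sub_error_rate = 0.001,
      class_mix = c(wildtype = 0.30, internick_deletion = 0.413,
                    nhej_indel = 0.139, vector_insertion = 0.098,
                    templated_insertion = 0.05)),
    itr_hotspot = list(
      n_reads = 1500L, seed = 214L, sub_error_rate = 0,
      itr_breakpoint_bias = 0.8,
      class_mix = c(wildtype = 0.5, vector_insertion = 0.5)))
}

#' Generate the standard fixture bundles
#'
#' Builds the synthetic locus and vector references and the four
#' standard read bundles (`clean_wt`, `paired_nickase_mix`,
#' `nuclease_mix`, `itr_hotspot`) at pinned seeds, and writes a
#' manifest pinning parameters, seeds and file checksums. Regeneration
#' reproduces the checksums exactly.
#'
#' @param target_dir output directory.
#' @param locus_seed,vector_seed seeds for the shared references.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
make_fixtures <- function(target_dir, locus_seed = 101L,
                          vector_seed = 7L) {
  dir.create(target_dir, showWarnings = FALSE, recursive = TRUE)
  locus <- build_synthetic_locus(seed = locus_seed)
  vec <- build_synthetic_vector(seed = vector_seed)
  ref_dir <- file.path(target_dir, "refs")
  ref_paths <- write_references(locus$amplicon, vec, locus$pair, ref_dir)
  manifest <- list(references = list(
    locus_seed = locus_seed, vector_seed = vector_seed,
    checksums = as.list(tools::md5sum(unlist(ref_paths)))))
  for (name in names(fixture_specs())) {
    spec <- fixture_specs()[[name]]
    cfg <- do.call(sim_config, spec)
    out <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair,
                            file.path(target_dir, name), prefix = name)
    files <- c(out$fastq, out$truth_path)
    manifest[[name]] <- list(
      parameters = spec[setdiff(names(spec), "seed")],
      seed = spec$seed,
      class_counts = as.list(out$class_counts),
      checksums = as.list(tools::md5sum(files)))
  }
  path <- file.path(target_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run configuration for a generated fixture bundle
#'
#' Convenience wrapper wiring a [make_fixtures()] bundle into
#' [run_config()].
#' @param fixture_dir directory passed to [make_fixtures()].
#' @param name fixture name.
#' @param out_dir pipeline output directory.
#' @param ... overrides passed to [run_config()].
#' @return a `RunConfig`.
#' @export
fixture_run_config <- function(fixture_dir, name, out_dir, ...) {
  run_config(
    reads = file.path(fixture_dir, name, paste0(name, ".fastq")),
    amplicon = file.path(fixture_dir, "refs", "amplicon.fa"),
    vector = file.path(fixture_dir, "refs", "vector.fa"),
    guides = file.path(fixture_dir, "refs", "guides.tsv"),
    vector_features = file.path(fixture_dir, "refs",
                                "vector_features.tsv"),
    out_dir = out_dir, ...)
}
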