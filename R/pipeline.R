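#' Phase an assembly graph with proximity-ligation contacts
#'
#' The full contact workflow: read the GFA, identify bubbles (from an
#' annotation sidecar when given, otherwise by homology search), parse the
#' alignments into a contact graph, optimize the phase by sampled greedy
#' max-cut, chain and unzip the phased bubbles, and write the outputs:
#' `phase.tsv`, `chains.tsv`, `haplotypes.gfa` (input graph plus haplotype
#' P lines), per-haplotype FASTA, and a `manifest.json` recording the
#' resolved configuration so the run is reproducible.
#'
#' @param gfa Path to a blunt GFA1 file (or an [assembly_graph()]).
#' @param alignments Path to SAM/BAM of proximity-ligation reads mapped to
#'   the graph segments (or a records tibble from [parse_alignments()]).
#' @param out_dir Output directory (created if needed).
#' @param annotation Optional bubble annotation sidecar (TSV path or
#'   tibble); when `NULL`, bubbles are detected by homology.
#' @param contacts_cfg A [contact_config()].
#' @param sampler A [sampler_config()].
#' @param sketch A [sketch_params()].
#' @return Invisibly, a list with `graph`, `bubbles`, `contacts`, `fit`,
#'   `chains`, `hap_paths`, `summary`, `files`.
#' @export
phase_contacts <- function(gfa, alignments, out_dir,
                           annotation = NULL,
                           contacts_cfg = contact_config(),
                           sampler = sampler_config(),
                           sketch = sketch_params()) {
  graph <- if (inherits(gfa, "assembly_graph")) gfa else read_gfa(gfa)
  bubbles <- if (is.null(annotation)) {
    detect_bubbles(graph, sketch)
  } else {
    bubbles_from_annotation(graph, annotation)
  }
  records <- if (is.character(alignments)) {
    parse_alignments(alignments, contacts_cfg, graph)
  } else {
    tibble::as_tibble(alignments)
  }
  contacts <- build_contact_graph(records, contacts_cfg)
  fit <- phase_by_contacts(bubbles, contacts, sampler)
  finish_phasing(graph, bubbles, fit, out_dir,
                 manifest = list(workflow = "phase_contacts",
                                 contacts = unclass(contacts_cfg),
                                 sampler = unclass(sampler),
                                 sketch = if (is.null(annotation))
                                   unclass(sketch) else NULL,
                                 n_records = nrow(records),
                                 n_contact_edges = nrow(contacts)),
                 extra = list(contacts = contacts, records = records))
}

#' Phase an assembly graph with parental k-mers
#'
#' Trio workflow: read the GFA, identify bubbles, build parent-unique
#' k-mer sets from the two parental count dumps, call each bubble by
#' majority vote, then chain and unzip. Outputs match [phase_contacts()];
#' the phase is globally anchored (haplotype 0 = paternal).
#'
#' @param gfa Path to a blunt GFA1 file (or an [assembly_graph()]).
#' @param paternal_kmers,maternal_kmers K-mer dump paths (or count
#'   tibbles).
#' @param out_dir Output directory.
#' @param annotation Optional bubble annotation sidecar; homology search
#'   otherwise.
#' @param trio_cfg A [trio_config()].
#' @param sketch A [sketch_params()].
#' @return Invisibly, a list as in [phase_contacts()] plus `votes`.
#' @export
phase_trio <- function(gfa, paternal_kmers, maternal_kmers, out_dir,
                       annotation = NULL, trio_cfg = trio_config(),
                       sketch = sketch_params()) {
  graph <- if (inherits(gfa, "assembly_graph")) gfa else read_gfa(gfa)
  bubbles <- if (is.null(annotation)) {
    detect_bubbles(graph, sketch)
  } else {
    bubbles_from_annotation(graph, annotation)
  }
  pat <- if (is.character(paternal_kmers)) read_kmer_dump(paternal_kmers)
    else tibble::as_tibble(paternal_kmers)
  mat <- if (is.character(maternal_kmers)) read_kmer_dump(maternal_kmers)
    else tibble::as_tibble(maternal_kmers)
  sets <- build_parent_sets(pat, mat, trio_cfg)
  fit <- phase_by_trio(bubbles, graph, sets, trio_cfg)
  res <- finish_phasing(graph, bubbles, fit, out_dir,
                        manifest = list(workflow = "phase_trio",
                                        trio = unclass(trio_cfg),
                                        n_paternal_unique =
                                          length(sets$paternal_unique),
                                        n_maternal_unique =
                                          length(sets$maternal_unique)),
                        extra = list(votes = fit$votes))
  res
}

# shared tail of both phasing workflows: chain, unzip, write everything
finish_phasing <- function(graph, bubbles, fit, out_dir, manifest = list(),
                           extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- classify_nodes(graph, bubbles)
  chains <- find_chains(graph, labels, bubbles)
  hap_paths <- unzip_chains(chains, fit, graph)
  summ <- chain_summary(chains, hap_paths, graph)
  files <- c(
    phase = file.path(out_dir, "phase.tsv"),
    chains = file.path(out_dir, "chains.tsv"),
    gfa = file.path(out_dir, "haplotypes.gfa"),
    manifest = file.path(out_dir, "manifest.json"))
  write_phase_table(fit, files[["phase"]])
  readr::write_tsv(summ, files[["chains"]], progress = FALSE)
  write_gfa(graph_with_haplotype_paths(graph, hap_paths), files[["gfa"]])
  fasta <- write_haplotype_fasta(hap_paths, graph,
                                 file.path(out_dir, "haplotypes"))
  manifest$package_version <- as.character(utils::packageVersion("hapchain"))
  manifest$n_bubbles <- nrow(fit$bubbles)
  manifest$n_chains <- dplyr::n_distinct(chains$chain_id)
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(list(graph = graph, bubbles = bubbles, fit = fit,
                   chains = chains, hap_paths = hap_paths, summary = summ,
                   files = c(files, fasta)), extra))
}

#' Contact-level QC of proximity-ligation alignments
#'
#' Computes the per-read contact statistics and, when a diploid truth is
#' given, the per-mapQ signal-ratio table, writing both as TSV when an
#' output directory is provided. Supplementary alignments are kept by
#' default here (Pore-C subreads commonly arrive as supplementary
#' records); disable via `contacts_cfg`.
#'
#' @param alignments SAM/BAM path or a records tibble.
#' @param truth Optional diploid truth (tibble `contig`, `haplotype` or TSV
#'   path).
#' @param out_dir Optional output directory.
#' @param contacts_cfg A [contact_config()]; default keeps supplementary
#'   records and requires mapQ > 0.
#' @return A list with `stats` ([contact_stats()]) and `signal_ratio` (or
#'   `NULL`).
#' @export
evaluate_contact_qc <- function(alignments, truth = NULL, out_dir = NULL,
                                contacts_cfg = contact_config(
                                  include_supplementary = TRUE)) {
  records <- if (is.character(alignments)) {
    parse_alignments(alignments, contacts_cfg)
  } else {
    tibble::as_tibble(alignments)
  }
  stats <- contact_stats(records)
  sr <- if (!is.null(truth)) signal_ratio(records, truth) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(stats$alignments_per_read,
                     file.path(out_dir, "alignments_per_read.tsv"),
                     progress = FALSE)
    readr::write_tsv(stats$lengths,
                     file.path(out_dir, "alignment_lengths.tsv"),
                     progress = FALSE)
    if (!is.null(sr)) {
      readr::write_tsv(sr, file.path(out_dir, "signal_ratio.tsv"),
                       progress = FALSE)
    }
  }
  list(stats = stats, signal_ratio = sr)
}

#' Generate a synthetic fixture bundle on disk
#'
#' Runs the synthetic generator and writes everything a phasing run (and
#' its evaluation) consumes: the GFA, a SAM of simulated contacts, parental
#' k-mer dumps, and the truth tables (bubble annotation, per-bubble
#' orientation, per-segment haplotype, chain fragments), plus a manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `sim` object, the contact records
#'   and the file paths.
#' @export
simulate_fixture <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_diploid_graph(config)
  records <- simulate_contacts(sim)
  trio <- simulate_trio_kmers(sim)
  files <- c(gfa = file.path(out_dir, "assembly.gfa"),
             sam = file.path(out_dir, "contacts.sam"),
             annotation = file.path(out_dir, "truth_bubbles.tsv"),
             phase = file.path(out_dir, "truth_phase.tsv"),
             haplotypes = file.path(out_dir, "truth_haplotypes.tsv"),
             chains = file.path(out_dir, "truth_chains.tsv"),
             paternal = file.path(out_dir, "paternal_kmers.tsv"),
             maternal = file.path(out_dir, "maternal_kmers.tsv"),
             parent_truth = file.path(out_dir, "truth_parent_side.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_gfa(sim$graph, files[["gfa"]])
  write_sam(records, sim$graph, files[["sam"]])
  readr::write_tsv(sim$bubbles, files[["annotation"]], col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(sim$bubble_phase, files[["phase"]], progress = FALSE)
  readr::write_tsv(sim$phase, files[["haplotypes"]], progress = FALSE)
  readr::write_tsv(sim$chains, files[["chains"]], progress = FALSE)
  write_kmer_dump(trio$paternal, files[["paternal"]])
  write_kmer_dump(trio$maternal, files[["maternal"]])
  readr::write_tsv(trio$bubble_parent, files[["parent_truth"]],
                   progress = FALSE)
  jsonlite::write_json(
    c(unclass(config),
      list(package_version =
             as.character(utils::packageVersion("hapchain")))),
    files[["manifest"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, records = records, trio = trio, files = files))
}
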