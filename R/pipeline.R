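#' Run the full T4SS detection and characterisation pipeline
#'
#' Composes every stage on in-memory tables: quality gate, hit filtering,
#' component calling, anchored neighbourhood analysis (companion filter,
#' positional abundance, per-category association, contig-end report,
#' functional-context families), pilin-array detection with identity
#' statistics, greedy clustering of anchor-window proteins, and (when a
#' tree is supplied) patristic provenance classification. All reports are
#' written as TSV under `out_dir` together with a `manifest.tsv` listing
#' each file with its MD5 content hash, so two runs on identical inputs
#' produce identical manifests. Stage failures abort with the stage name;
#' a dataset without any anchor calls yields empty neighbourhood reports
#' with a warning, and a missing tree is noted in the manifest rather than
#' an error.
#'
#' @param cds CDS tibble (see [read_genome_annotation()] /
#'   [simulate_dataset()]).
#' @param qc Assembly table with `assembly_id`, `class_label`,
#'   `completeness`, `contamination`.
#' @param hits Profile hit tibble across all profile sets.
#' @param out_dir Output directory (created if needed).
#' @param tree Optional ape `phylo` of anchor-gene homologues.
#' @param tree_labels Optional tibble with `leaf`, `class_label` matching
#'   `tree` (defaults to parsing the tip labels).
#' @param k Window radius in CDS (default 20).
#' @param max_i_evalue,min_profile_coverage Hit filter thresholds.
#' @param anchor_category Anchor component category (default `"VirB4"`).
#' @param functional_sets Profile sets treated as functional-family
#'   databases for the context table.
#' @param mapping Profile-to-component mapping (default
#'   [component_mapping()]).
#' @return Invisibly, a list with every report tibble plus the manifest.
#' @export
run_pipeline <- function(cds, qc, hits, out_dir,
                         tree = NULL, tree_labels = NULL, k = 20,
                         max_i_evalue = 0.001, min_profile_coverage = 0.5,
                         anchor_category = "VirB4",
                         functional_sets = c("Pfam", "NCBIFAM", "TIGRFAM"),
                         mapping = component_mapping()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  out <- list()

  out$qc <- stage("qc", qc_gate(qc))
  kept <- dplyr::filter(out$qc, .data$passes)
  message(sprintf("qc: %d/%d assemblies pass the quality gate",
                  nrow(kept), nrow(out$qc)))
  cds <- dplyr::semi_join(cds, kept, by = "assembly_id")

  out$filtered_hits <- stage("filter", {
    fh <- filter_hits(hits, max_i_evalue = max_i_evalue,
                      min_profile_coverage = min_profile_coverage)
    dplyr::semi_join(fh, dplyr::select(cds, "protein_id"),
                     by = "protein_id")
  })
  t4ss_sets <- unique(mapping$profile_set)
  out$calls <- stage("call", {
    th <- dplyr::filter(out$filtered_hits,
                        .data$profile_set %in% t4ss_sets) |>
      dplyr::semi_join(mapping, by = c("profile_set", "profile_name"))
    assign_components(th, mapping = mapping)
  })
  message(sprintf("call: %d component calls on %d proteins",
                  nrow(out$calls), dplyr::n_distinct(out$calls$protein_id)))

  anchors <- dplyr::filter(out$calls, .data$category == anchor_category)
  asm_class <- dplyr::select(out$qc, "assembly_id", "class_label")
  out$class_presence <- stage("presence", {
    cds |>
      dplyr::filter(!is.na(.data$contig_id)) |>
      dplyr::semi_join(anchors, by = "protein_id") |>
      dplyr::distinct(.data$assembly_id) |>
      dplyr::mutate(has_anchor = TRUE) |>
      dplyr::right_join(kept, by = "assembly_id") |>
      dplyr::group_by(.data$class_label) |>
      dplyr::summarise(
        n_genomes = dplyr::n(),
        n_with_anchor = sum(!is.na(.data$has_anchor)),
        pct_with_anchor = count_percentage(sum(!is.na(.data$has_anchor)),
                                           dplyr::n()),
        .groups = "drop")
  })

  if (nrow(anchors) == 0) {
    rlang::warn("no anchor-category calls: neighbourhood reports are empty")
    out$windows <- tibble::tibble(anchor_protein = character(),
                                  assembly_id = character(),
                                  contig_id = character(),
                                  offset = integer(),
                                  protein_id = character(),
                                  index = integer())
    out$positional_abundance <- tibble::tibble(offset = integer(),
                                               category = character(),
                                               n = integer())
    out$association <- tibble::tibble()
    out$contig_end <- tibble::tibble()
    out$context_families <- tibble::tibble()
    out$arrays <- tibble::tibble()
    out$clusters <- tibble::tibble()
    near_end_summary <- tibble::tibble(n_anchors = 0L, n_near_end = 0L,
                                       pct_near_end = NA_real_)
  } else {
    out$windows <- stage("neighborhood",
                         extract_neighborhoods(cds, anchors, k = k))
    assoc_windows <- stage(
      "companion", anchors_with_companion(out$windows, out$calls,
                                          anchor_category = anchor_category))
    out$positional_abundance <- stage(
      "abundance", positional_abundance(assoc_windows, out$calls, k = k))
    cats <- setdiff(unique(out$calls$category), c(anchor_category, "Other"))
    out$association <- stage("association", {
      purrr::map(sort(cats), function(cat) {
        association_summary(out$calls, out$windows, cat)
      }) |> dplyr::bind_rows()
    })
    out$contig_end <- stage("contig_end",
                            anchor_truncation(cds, anchors, k = k))
    near_end_summary <- tibble::tibble(
      n_anchors = nrow(out$contig_end),
      n_near_end = sum(out$contig_end$near_end),
      pct_near_end = count_percentage(sum(out$contig_end$near_end),
                                      nrow(out$contig_end)))
    message(sprintf(
      "contig ends: %d/%d anchors (%.1f%%) within %d CDS of a contig end",
      near_end_summary$n_near_end, near_end_summary$n_anchors,
      near_end_summary$pct_near_end, k))
    out$context_families <- stage("context", {
      fh <- dplyr::filter(out$filtered_hits,
                          .data$profile_set %in% functional_sets)
      context_family_table(out$windows, fh, asm_class)
    })
    out$arrays <- stage("arrays", {
      arr <- detect_arrays(cds, out$calls)
      if (nrow(arr) > 0 && any(!is.na(cds$aa_seq))) {
        arr <- array_identity_stats(
          arr, dplyr::filter(cds, !is.na(.data$aa_seq)))
      }
      arr
    })
    out$clusters <- stage("cluster", {
      wseqs <- cds |>
        dplyr::semi_join(out$windows, by = "protein_id") |>
        dplyr::filter(!is.na(.data$aa_seq)) |>
        dplyr::distinct(.data$protein_id, .data$aa_seq)
      if (nrow(wseqs) > 0) greedy_cluster(wseqs) else tibble::tibble()
    })
  }

  if (!is.null(tree)) {
    out$provenance <- stage("provenance", {
      labs <- tree_labels %||% parse_leaf_labels(tree$tip.label)
      provenance_analysis(tree, labs)
    })
    out$provenance_records <- out$provenance$records
    out$provenance_summary <- out$provenance$summary
  }

  # ---- write reports + manifest -----------------------------------------
  write_report <- function(df, name) {
    listcols <- vapply(df, is.list, logical(1))
    for (cl in names(listcols)[listcols]) {
      df[[cl]] <- vapply(df[[cl]], paste, character(1), collapse = ",")
    }
    readr::write_tsv(df, file.path(out_dir, name))
    name
  }
  files <- c(
    write_report(out$qc, "qc_gate.tsv"),
    write_report(out$calls, "component_calls.tsv"),
    write_report(out$class_presence, "class_presence.tsv"),
    write_report(out$windows, "anchor_windows.tsv"),
    write_report(out$positional_abundance, "positional_abundance.tsv"),
    write_report(out$association, "association_summary.tsv"),
    write_report(out$contig_end, "contig_end.tsv"),
    write_report(near_end_summary, "near_end_summary.tsv"),
    write_report(out$context_families, "context_families.tsv"),
    write_report(out$arrays, "pilin_arrays.tsv"),
    write_report(out$clusters, "clusters.tsv")
  )
  if (!is.null(tree)) {
    files <- c(files,
               write_report(out$provenance_records, "provenance_records.tsv"),
               write_report(out$provenance_summary, "provenance_summary.tsv"))
  } else {
    message("no tree supplied: provenance stage skipped")
  }
  skipped <- if (is.null(tree)) "provenance" else ""
  out$manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stage_skipped = skipped
  )
  readr::write_tsv(out$manifest, file.path(out_dir, "manifest.tsv"))
  message(sprintf("wrote %d report files to %s", length(files), out_dir))
  invisible(out)
}
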