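# Dataset summaries: totals, completeness bookkeeping, per-species class
# repertoires, and the phylogeny-input domain count.

norm_class <- function(x) {
  # collapse variant letters (class-1A -> class-1); leave other labels alone
  sub("^(class-[1-4])[A-Za-z]$", "\\1", x)
}

CLASS_LEVELS <- c("class-1", "class-2", "class-3", "class-4", "unclassified")

#' Summarize a coronin dataset
#'
#' Counts sequences, species, completeness categories and pseudogenes, and
#' tabulates the per-species class repertoire. Pseudogenes are counted
#' separately and excluded from the completeness totals; a pseudogene whose
#' record carries no sequence is tracked through the optional `has_sequence`
#' column.
#'
#' @param records Record tibble with `id`, `species`, `class_label`,
#'   `completeness`, `pseudogene`, and optionally `from_wgs` and
#'   `has_sequence` logical columns.
#' @return A `coro_summary` list: `$totals` (one-row tibble) and
#'   `$per_species_class_counts` (species x class tibble).
#' @export
summarize_dataset <- function(records) {
  if (nrow(records) == 0) {
    return(structure(list(
      totals = tibble(n_sequences = 0L, n_from_wgs = 0L, n_species = 0L,
                      n_complete = 0L, n_partial = 0L, n_fragment = 0L,
                      n_pseudogenes = 0L, n_pseudogenes_without_sequence = 0L),
      per_species_class_counts = tibble(species = character(0))
    ), class = "coro_summary"))
  }
  pseudo <- !is.na(records$pseudogene) & records$pseudogene
  has_seq <- if ("has_sequence" %in% names(records)) records$has_sequence else TRUE
  from_wgs <- if ("from_wgs" %in% names(records)) records$from_wgs else NA
  comp <- records$completeness[!pseudo]
  totals <- tibble(
    n_sequences = nrow(records),
    n_from_wgs = sum(from_wgs %in% TRUE),
    n_species = dplyr::n_distinct(records$species[!is.na(records$species)]),
    n_complete = sum(comp %in% "Complete"),
    n_partial = sum(comp %in% "Partial"),
    n_fragment = sum(comp %in% "Fragment"),
    n_pseudogenes = sum(pseudo),
    n_pseudogenes_without_sequence = sum(pseudo & !(has_seq %in% TRUE))
  )
  per_species <- records |>
    filter(!is.na(.data$species), !is.na(.data$class_label)) |>
    mutate(class = factor(norm_class(.data$class_label), levels = CLASS_LEVELS)) |>
    count(.data$species, .data$class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  structure(list(totals = totals, per_species_class_counts = per_species),
            class = "coro_summary")
}

#' @export
print.coro_summary <- function(x, ...) {
  cat("<coro_summary>\n")
  print(x$totals)
  cat(sprintf("per-species repertoire: %d species\n", nrow(x$per_species_class_counts)))
  invisible(x)
}

#' Number of coronin domains entering the phylogeny
#'
#' Only full-length and partial sequences enter the domain phylogeny, and the
#' two coronin domains of each tandem (class-3) coronin are counted
#' separately, so the input size is `#Complete + #Partial` plus one extra
#' domain per complete-or-partial class-3 record. Pseudogenes are excluded
#' before counting.
#'
#' @param records Record tibble with `class_label`, `completeness`,
#'   `pseudogene`.
#' @return Integer domain count.
#' @export
phylogeny_domain_count <- function(records) {
  pseudo <- !is.na(records$pseudogene) & records$pseudogene
  keep <- !pseudo & records$completeness %in% c("Complete", "Partial")
  tandem <- keep & norm_class(records$class_label) %in% "class-3"
  as.integer(sum(keep) + sum(tandem))
}
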