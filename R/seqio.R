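# Readers/writers for the formats the pipeline consumes: protein FASTA,
# aligned FASTA, GFF3 gene structures with their genomic sequence, Newick
# trees, and tabular domain annotations.

VALID_AA <- paste0(paste(AA20, collapse = ""), "X")

parse_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  tibble(
    id = parts[1],
    species = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA_character_,
    class_label = if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else NA_character_
  )
}

check_protein_alphabet <- function(protein, id, allow_gaps = FALSE) {
  alphabet <- if (allow_gaps) paste0(VALID_AA, "-") else VALID_AA
  bad <- regexpr(sprintf("[^%s]", alphabet), protein)
  if (bad > 0) {
    abort(sprintf("illegal residue '%s' in record '%s' at position %d",
                  substr(protein, bad, bad), id, bad))
  }
  invisible(TRUE)
}

#' Read coronin protein sequences from FASTA
#'
#' Headers may carry metadata in the pipeline's `id|species|class` dialect;
#' plain headers are read with the metadata fields left `NA`. Sequences must
#' be ungapped and restricted to the 20 amino acids plus `X`.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with one row per record and columns `id`, `species`,
#'   `protein`, `class_label`, `completeness`, `pseudogene`, in file order.
#' @export
read_coronin_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- sub("\\s.*$", "", names(aa))
  meta <- list_rbind(map(headers, parse_header))
  if (anyDuplicated(meta$id)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(meta$id[duplicated(meta$id)]), collapse = ", ")))
  }
  prot <- toupper(as.character(aa))
  for (i in seq_along(prot)) {
    if (!nzchar(prot[i])) abort(sprintf("empty sequence for record '%s'", meta$id[i]))
    check_protein_alphabet(prot[i], meta$id[i])
  }
  tibble(
    id = meta$id, species = meta$species, protein = unname(prot),
    class_label = meta$class_label,
    completeness = NA_character_, pseudogene = NA
  )
}

#' Write coronin records to FASTA
#'
#' @param records Tibble as returned by [read_coronin_fasta()].
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_coronin_fasta <- function(records, path, width = 60L) {
  lines <- unlist(pmap(records[c("id", "species", "class_label", "protein")],
    function(id, species, class_label, protein) {
      header <- id
      if (!is.na(species) || !is.na(class_label)) {
        header <- paste(id, species %|na|% "", class_label %|na|% "", sep = "|")
        header <- sub("\\|+$", "", header)
      }
      c(paste0(">", header), wrap_seq(protein, width))
    }))
  writeLines(lines, path)
  invisible(path)
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

wrap_seq <- function(s, width) {
  if (nchar(s) == 0) return(character())
  substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' Rows must all have the same number of columns; a row consisting entirely
#' of gaps is accepted but reported via a warning and the `all_gap_rows`
#' attribute.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `seq` (gapped rows) and attribute
#'   `aln_length` (number of columns).
#' @export
read_alignment <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate alignment row id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  widths <- Biostrings::width(aa)
  if (length(unique(widths)) > 1) {
    off <- widths != widths[1]
    abort(sprintf("ragged alignment: row '%s' has %d columns, expected %d",
                  ids[which(off)[1]], widths[which(off)[1]], widths[1]))
  }
  rows <- toupper(as.character(aa))
  for (i in seq_along(rows)) check_protein_alphabet(rows[i], ids[i], allow_gaps = TRUE)
  all_gap <- ids[grepl("^-+$", rows)]
  if (length(all_gap)) {
    warn(sprintf("alignment row(s) consisting entirely of gaps: %s",
                 paste(all_gap, collapse = ", ")))
  }
  out <- tibble(id = ids, seq = unname(rows))
  attr(out, "aln_length") <- unname(widths[1])
  attr(out, "all_gap_rows") <- all_gap
  out
}

#' Write an alignment to aligned FASTA
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  lines <- unlist(map2(aln$id, aln$seq, function(id, s) c(paste0(">", id), wrap_seq(s, width))))
  writeLines(lines, path)
  invisible(path)
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Read gene structures from GFF3 plus genomic FASTA
#'
#' Consumes CDS features grouped by their `Parent` (or, failing that, `ID`)
#' attribute. Coordinates are converted from GFF3 1-based closed to 0-based
#' half-open and exons are ordered in transcript orientation, so exon 1 is
#' always the 5'-most coding exon of the transcript regardless of strand.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param genomic_fasta Path to the FASTA of the genomic sequences the GFF3
#'   coordinates refer to.
#' @return A `coro_genes` list with `$exons`, a tibble (`gene_id`, `seqid`,
#'   `strand`, `exon`, `start`, `end`) where `exon` counts 5' to 3' along the
#'   transcript, and `$genomic`, a named character vector of genomic
#'   sequences.
#' @export
read_gene_structures <- function(gff_path, genomic_fasta) {
  stopifnot(file.exists(gff_path), file.exists(genomic_fasta))
  gr <- as.data.frame(rtracklayer::import(gff_path))
  gr <- gr[gr$type == "CDS", ]
  if (nrow(gr) == 0) abort("no CDS features in GFF3 file")
  parent <- as.character(gr$Parent)
  if (length(parent) == 0 || all(!nzchar(parent) | is.na(parent))) parent <- as.character(gr$ID)
  exons <- tibble(
    gene_id = parent,
    seqid = as.character(gr$seqnames),
    strand = as.character(gr$strand),
    start = gr$start - 1L,  # to 0-based half-open
    end = gr$end
  )
  genomic <- toupper(as.character(Biostrings::readDNAStringSet(genomic_fasta)))
  names(genomic) <- sub("\\s.*$", "", names(genomic))
  new_coro_genes(exons, genomic)
}

#' Build a `coro_genes` object from an exon table and genomic sequences
#'
#' @param exons Tibble with columns `gene_id`, `seqid`, `strand`, `start`,
#'   `end` (0-based half-open genomic intervals).
#' @param genomic Named character vector of genomic sequences.
#' @return A validated `coro_genes` list.
#' @export
new_coro_genes <- function(exons, genomic) {
  exons <- exons |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      exon = if (.data$strand[1] == "+") row_number() else rev(row_number())
    ) |>
    arrange(.data$exon, .by_group = TRUE) |>
    ungroup()
  for (g in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == g, ]
    sq <- genomic[[ex$seqid[1]]]
    if (is.null(sq) || is.na(sq)) abort(sprintf("gene '%s': genomic sequence '%s' missing", g, ex$seqid[1]))
    if (any(ex$end > nchar(sq)) || any(ex$start < 0)) {
      abort(sprintf("gene '%s': exon beyond genomic sequence end", g))
    }
    gx <- ex[order(ex$start), ]
    if (any(gx$start[-1] < gx$end[-nrow(gx)])) {
      abort(sprintf("gene '%s': overlapping exons", g))
    }
    if (nrow(gx) > 1 && any(gx$start[-1] - gx$end[-nrow(gx)] < 4)) {
      abort(sprintf("gene '%s': intron shorter than 4 nt", g))
    }
  }
  structure(list(exons = exons, genomic = genomic), class = "coro_genes")
}

#' @export
print.coro_genes <- function(x, ...) {
  cat(sprintf("<coro_genes> %d gene(s), %d exon(s), %d genomic sequence(s)\n",
              length(unique(x$exons$gene_id)), nrow(x$exons), length(x$genomic)))
  invisible(x)
}

#' Write gene structures to GFF3 and genomic FASTA
#'
#' @param genes A `coro_genes` object.
#' @param gff_path Output GFF3 path.
#' @param fasta_path Output genomic FASTA path (optional).
#' @return `gff_path`, invisibly.
#' @export
write_gene_structures <- function(genes, gff_path, fasta_path = NULL) {
  ex <- genes$exons[order(genes$exons$gene_id, genes$exons$start), ]
  lines <- c("##gff-version 3",
    sprintf("%s\tcorofam\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
            ex$seqid, ex$start + 1L, ex$end, ex$strand, ex$gene_id))
  writeLines(lines, gff_path)
  if (!is.null(fasta_path)) {
    fa <- unlist(map2(names(genes$genomic), unname(genes$genomic),
                      function(id, s) c(paste0(">", id), wrap_seq(s, 60L))))
    writeLines(fa, fasta_path)
  }
  invisible(gff_path)
}

#' Read a phylogenetic tree from Newick
#'
#' Polytomies are preserved; leaf names must be unique.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  stopifnot(file.exists(path))
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) abort(sprintf("failed to parse Newick in '%s'", path))
  if (anyDuplicated(tr$tip.label)) abort("duplicate leaf names in tree")
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read domain annotations from TSV
#'
#' External (non-coronin) domain predictions are consumed as annotations with
#' columns `seq_id`, `domain_name`, `start`, `end`, `source` (1-based
#' inclusive residue coordinates).
#'
#' @param path TSV file.
#' @return A tibble of domain hits with `source` set as given.
#' @export
read_domain_annotations <- function(path) {
  stopifnot(file.exists(path))
  ann <- readr::read_tsv(path, col_types = readr::cols(
    seq_id = readr::col_character(), domain_name = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    source = readr::col_character()))
  stopifnot(all(ann$start >= 1), all(ann$end >= ann$start))
  ann
}

#' Write domain annotations to TSV
#'
#' @param hits Domain-hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_annotations <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}
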