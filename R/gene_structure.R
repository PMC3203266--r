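# Intron positions and phases, splice-junction validation, projection of
# introns onto protein alignments, exon-border conservation flags,
# mutually-exclusive-exon detection, and the completeness / pseudogene rules.

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

gene_exons <- function(genes, gene_id) {
  ex <- genes$exons[genes$exons$gene_id == gene_id, ]
  if (nrow(ex) == 0) abort(sprintf("unknown gene '%s'", gene_id))
  ex[order(ex$exon), ]
}

exon_sequences <- function(genes, gene_id) {
  ex <- gene_exons(genes, gene_id)
  sq <- genes$genomic[[ex$seqid[1]]]
  seqs <- substring(sq, ex$start + 1L, ex$end)
  if (ex$strand[1] == "-") seqs <- vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
  seqs
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the coding exons in transcript orientation (minus-strand
#' genes are reverse-complemented), giving the mRNA-sense CDS.
#'
#' @param genes A `coro_genes` object.
#' @param gene_id Gene to splice.
#' @return A single nucleotide string.
#' @export
spliced_cds <- function(genes, gene_id) {
  paste(exon_sequences(genes, gene_id), collapse = "")
}

#' Translate a spliced CDS
#'
#' Translates in frame from the first nucleotide; a trailing incomplete codon
#' is dropped. Stop codons appear as `*`.
#'
#' @inheritParams spliced_cds
#' @return An amino-acid string (possibly containing `*`).
#' @export
translate_cds <- function(genes, gene_id) {
  cds <- spliced_cds(genes, gene_id)
  n <- (nchar(cds) %/% 3L) * 3L
  if (n == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1, n)),
                                     if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Intron positions and splice phases of gene structures
#'
#' For every intron, the cumulative number of coding nucleotides upstream
#' (`cds_nt_before`), the phase (`cds_nt_before mod 3`: 0 between codons, 1 or
#' 2 inside a codon) and the 1-based index of the interrupted or
#' last-completed protein residue. Single-exon genes contribute no rows.
#'
#' @param genes A `coro_genes` object.
#' @return A tibble (`gene_id`, `intron_index`, `cds_nt_before`, `residue`,
#'   `phase`) ordered 5' to 3' within each gene.
#' @export
intron_marks <- function(genes) {
  out <- map(unique(genes$exons$gene_id), function(g) {
    ex <- gene_exons(genes, g)
    if (nrow(ex) < 2) return(NULL)
    len <- ex$end - ex$start
    cum <- cumsum(len)[-nrow(ex)]
    tibble(
      gene_id = g,
      intron_index = seq_along(cum),
      cds_nt_before = as.integer(cum),
      residue = as.integer(ceiling(cum / 3)),
      phase = as.integer(cum %% 3)
    )
  })
  bind_rows(out)
}

classify_splice <- function(donor, acceptor) {
  dplyr::case_when(
    donor == "GT" & acceptor == "AG" ~ "canonical",
    (donor == "GC" & acceptor == "AG") | (donor == "AT" & acceptor == "AC") ~ "noncanonical",
    TRUE ~ "violation"
  )
}

#' Validate splice-junction dinucleotides
#'
#' Checks each intron's donor and acceptor dinucleotides in transcript
#' orientation: GT..AG is canonical, GC..AG and AT..AC are the accepted
#' noncanonical sites, anything else is a violation.
#'
#' @param genes A `coro_genes` object.
#' @return A tibble (`gene_id`, `intron_index`, `donor`, `acceptor`,
#'   `status`).
#' @export
validate_splice_sites <- function(genes) {
  out <- map(unique(genes$exons$gene_id), function(g) {
    ex <- gene_exons(genes, g)
    if (nrow(ex) < 2) return(NULL)
    sq <- genes$genomic[[ex$seqid[1]]]
    plus <- ex$strand[1] == "+"
    introns <- map_chr(seq_len(nrow(ex) - 1), function(i) {
      if (plus) {
        s <- substr(sq, ex$end[i] + 1L, ex$start[i + 1])
      } else {
        s <- revcomp(substr(sq, ex$end[i + 1] + 1L, ex$start[i]))
      }
      if (nchar(s) < 4) abort(sprintf("gene '%s': intron %d shorter than 4 nt", g, i))
      s
    })
    tibble(
      gene_id = g,
      intron_index = seq_along(introns),
      donor = substr(introns, 1, 2),
      acceptor = substr(introns, nchar(introns) - 1L, nchar(introns))
    )
  })
  out <- bind_rows(out)
  if (nrow(out)) out$status <- classify_splice(out$donor, out$acceptor)
  out
}

#' Map a protein residue to its alignment column
#'
#' @param row Gapped alignment row.
#' @param residue 1-based residue index in the ungapped sequence.
#' @return The 1-based alignment column.
#' @export
residue_to_column <- function(row, residue) {
  pos <- which(strsplit(row, "")[[1]] != "-")
  if (residue < 1 || residue > length(pos)) {
    abort(sprintf("residue %d beyond ungapped row length %d", residue, length(pos)))
  }
  pos[residue]
}

#' Map an alignment column back to a residue index
#'
#' Inverse of [residue_to_column()] on non-gap columns.
#'
#' @param row Gapped alignment row.
#' @param column 1-based alignment column; must not be a gap in `row`.
#' @return The 1-based residue index.
#' @export
column_to_residue <- function(row, column) {
  chars <- strsplit(row, "")[[1]]
  if (column < 1 || column > length(chars)) abort("column outside alignment")
  if (chars[column] == "-") abort(sprintf("column %d is a gap in this row", column))
  sum(chars[seq_len(column)] != "-")
}

#' Project intron marks onto a protein alignment
#'
#' Fills the `column` field of each intron mark with the alignment column of
#' its residue in the corresponding row, skipping gaps, so intron positions
#' of homologous genes become directly comparable.
#'
#' @param aln Alignment tibble (`id`, `seq`); row ids must match `gene_id`s.
#' @param marks Output of [intron_marks()].
#' @return `marks` with an added integer `column`.
#' @export
project_introns <- function(aln, marks) {
  rows <- setNames(aln$seq, aln$id)
  missing <- setdiff(unique(marks$gene_id), names(rows))
  if (length(missing)) {
    abort(sprintf("no alignment row for gene(s): %s", paste(missing, collapse = ", ")))
  }
  marks$column <- map_int(seq_len(nrow(marks)), function(i) {
    as.integer(residue_to_column(rows[[marks$gene_id[i]]], marks$residue[i]))
  })
  marks
}

#' Flag exon borders unsupported by homologs
#'
#' An intron mark is supported when at least `min_support` other genes carry
#' a mark of the same phase within `window` alignment columns; otherwise it
#' is flagged suspicious, mirroring the cross-species comparison used to
#' resolve doubtful exon-border predictions.
#'
#' @param marks Projected marks (with `column`), from [project_introns()].
#' @param min_support Minimum number of supporting homologs.
#' @param window Column tolerance either side.
#' @return A tibble (`gene_id`, `intron_index`, `column`, `phase`,
#'   `n_support`, `verdict`).
#' @export
flag_borders <- function(marks, min_support = 2L, window = 5L) {
  stopifnot(nrow(marks) > 0, "column" %in% names(marks))
  if (length(unique(marks$gene_id)) < 2) abort("need projected marks from at least 2 genes")
  n_support <- map_int(seq_len(nrow(marks)), function(i) {
    others <- marks[marks$gene_id != marks$gene_id[i], ]
    hits <- others$phase == marks$phase[i] & abs(others$column - marks$column[i]) <= window
    length(unique(others$gene_id[hits]))
  })
  tibble(
    gene_id = marks$gene_id, intron_index = marks$intron_index,
    column = marks$column, phase = marks$phase, n_support = n_support,
    verdict = ifelse(n_support < min_support, "suspicious", "supported")
  )
}

translate_in_phase <- function(nt, upstream_phase) {
  off <- (3L - upstream_phase) %% 3L
  nt <- substr(nt, off + 1L, nchar(nt))
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n)),
                                     if.fuzzy.codon = "X", no.init.codon = TRUE))
}

ungapped_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0)
  mean(strsplit(substr(a, 1, n), "")[[1]] == strsplit(substr(b, 1, n), "")[[1]])
}

#' Detect candidate mutually exclusive exon clusters
#'
#' Consecutive internal exons are clustered when they sit in the same splice
#' phase context (equal upstream phase and equal length mod 3, so either exon
#' fits the same flanking introns), their lengths agree within `len_tol`
#' relative tolerance, and the ungapped identity of their in-phase
#' translations reaches `min_identity` — the signature of an exon duplication
#' like the coronin-1D exon5a/exon5b pair.
#'
#' @param genes A `coro_genes` object.
#' @param min_identity Minimum translated identity between neighbours.
#' @param len_tol Maximum relative length difference.
#' @return A tibble (`gene_id`, `exon_from`, `exon_to`, `exon_indices`
#'   list-column, `pairwise_identity`, `upstream_phase`, `downstream_phase`);
#'   zero rows when nothing qualifies.
#' @export
detect_mxe <- function(genes, min_identity = 0.3, len_tol = 0.2) {
  out <- map(unique(genes$exons$gene_id), function(g) {
    ex <- gene_exons(genes, g)
    n <- nrow(ex)
    if (n < 3) return(NULL)
    len <- ex$end - ex$start
    cum_before <- c(0L, cumsum(len))[seq_len(n)]
    seqs <- exon_sequences(genes, g)
    internal <- 2:(n - 1)
    pair_ok <- logical(0); pair_id <- numeric(0)
    if (length(internal) > 1) {
      for (k in seq_len(length(internal) - 1)) {
        i <- internal[k]; j <- internal[k + 1]
        same_phase_ctx <- (len[i] %% 3L) == (len[j] %% 3L)
        len_close <- abs(len[i] - len[j]) / max(len[i], len[j]) <= len_tol
        p <- as.integer(cum_before[i] %% 3L)
        idy <- ungapped_identity(translate_in_phase(seqs[i], p),
                                 translate_in_phase(seqs[j], p))
        pair_ok[k] <- same_phase_ctx && len_close && idy >= min_identity
        pair_id[k] <- idy
      }
    }
    if (!any(pair_ok)) return(NULL)
    # maximal runs of qualifying consecutive pairs
    runs <- rle(pair_ok)
    pos <- cumsum(c(1, runs$lengths))
    clusters <- map(which(runs$values), function(r) {
      ks <- seq(pos[r], length.out = runs$lengths[r])
      idx <- internal[seq(ks[1], ks[length(ks)] + 1)]
      tibble(
        gene_id = g, exon_from = idx[1], exon_to = idx[length(idx)],
        exon_indices = list(idx),
        pairwise_identity = mean(pair_id[ks]),
        upstream_phase = as.integer(cum_before[idx[1]] %% 3L),
        downstream_phase = as.integer((cum_before[idx[1]] + len[idx[1]]) %% 3L)
      )
    })
    bind_rows(clusters)
  })
  bind_rows(out)
}

#' Categorize sequence completeness
#'
#' Sequences missing nothing are Complete, sequences missing up to 5% of the
#' expected length are Partials (they are not expected to influence the
#' phylogeny appreciably), and anything missing more is a Fragment.
#'
#' @param records Record tibble with `id` and `protein`.
#' @param expected_length Expected full-length residue count (scalar or one
#'   per record), e.g. the family median of complete homologs.
#' @return A tibble (`id`, `observed`, `expected`, `missing_fraction`,
#'   `completeness`).
#' @export
call_completeness <- function(records, expected_length) {
  stopifnot(all(expected_length > 0))
  obs <- nchar(records$protein)
  mf <- pmax(0, (expected_length - obs) / expected_length)
  tibble(
    id = records$id,
    observed = obs,
    expected = as.numeric(expected_length),
    missing_fraction = mf,
    completeness = dplyr::case_when(
      mf == 0 ~ "Complete",
      mf <= 0.05 ~ "Partial",
      TRUE ~ "Fragment"
    )
  )
}

#' Call pseudogenes from lesion counts
#'
#' Counts coding lesions per gene: in-frame stop codons in the spliced
#' translation (the terminal codon excluded) and frameshift events, i.e.
#' changes in the frame offset between observed intron phases and the
#' family-conserved expected phases, plus a terminal CDS length not returning
#' to frame. A gene is called a pseudogene when lesions reach
#' `lesion_threshold` (too many to attribute to sequencing error) or when at
#' least one lesion coincides with more than 20% missing sequence.
#'
#' @param genes A `coro_genes` object.
#' @param expected_phases Optional tibble (`gene_id`, `intron_index`,
#'   `phase`) of conserved intron phases; without it only the terminal
#'   frame check contributes to the frameshift count.
#' @param lesion_threshold Lesion count at which the verdict flips.
#' @param missing_fraction Scalar or per-gene named vector of missing
#'   sequence fraction.
#' @return A tibble (`gene_id`, `n_frameshifts`, `n_internal_stops`,
#'   `missing_fraction`, `pseudogene`).
#' @export
call_pseudogene <- function(genes, expected_phases = NULL, lesion_threshold = 3L,
                            missing_fraction = 0) {
  ids <- unique(genes$exons$gene_id)
  mf <- if (length(missing_fraction) == 1 && is.null(names(missing_fraction))) {
    setNames(rep(missing_fraction, length(ids)), ids)
  } else missing_fraction
  marks <- intron_marks(genes)
  out <- map(ids, function(g) {
    ex <- gene_exons(genes, g)
    total <- sum(ex$end - ex$start)
    gm <- marks[marks$gene_id == g, ]
    offsets <- integer(0)
    if (nrow(gm) > 0 && !is.null(expected_phases)) {
      exp_g <- expected_phases[expected_phases$gene_id == g, ]
      exp_ph <- exp_g$phase[match(gm$intron_index, exp_g$intron_index)]
      if (!anyNA(exp_ph)) offsets <- (gm$phase - exp_ph) %% 3L
    }
    last_off <- if (length(offsets)) offsets[length(offsets)] else 0L
    n_fs <- sum(offsets != dplyr::lag(offsets, default = 0L)) +
      as.integer((total %% 3L) != last_off)
    prot <- translate_cds(genes, g)
    codons <- strsplit(prot, "")[[1]]
    internal <- if (length(codons) > 1) codons[-length(codons)] else character(0)
    n_stop <- sum(internal == "*")
    lesions <- n_fs + n_stop
    tibble(
      gene_id = g,
      n_frameshifts = as.integer(n_fs),
      n_internal_stops = as.integer(n_stop),
      missing_fraction = unname(mf[[g]] %||% 0),
      pseudogene = lesions >= lesion_threshold ||
        (lesions >= 1 && (mf[[g]] %||% 0) > 0.2)
    )
  })
  bind_rows(out)
}
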