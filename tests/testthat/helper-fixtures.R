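# In-code fixture builders shared across the suite.

AA20_T <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")

rand_prot <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20_T, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# gene with given exon CDS lengths; introns 20 nt with chosen site dinucleotides
toy_genes <- function(exon_lens, strand = "+", cds = NULL, gene_id = "g1",
                      donors = "GT", acceptors = "AG", flank = 10L) {
  total <- sum(exon_lens)
  if (is.null(cds)) cds <- rand_dna(total)
  stopifnot(nchar(cds) == total)
  donors <- rep(donors, length.out = max(0, length(exon_lens) - 1))
  acceptors <- rep(acceptors, length.out = max(0, length(exon_lens) - 1))
  bnd <- cumsum(exon_lens)[-length(exon_lens)]
  starts <- c(1L, bnd + 1L); ends <- c(bnd, total)
  locus <- rand_dna(flank)
  ex_start <- integer(0); ex_end <- integer(0)
  for (i in seq_along(exon_lens)) {
    ex_start[i] <- nchar(locus)
    locus <- paste0(locus, substr(cds, starts[i], ends[i]))
    ex_end[i] <- nchar(locus)
    if (i < length(exon_lens)) {
      locus <- paste0(locus, donors[i], rand_dna(16), acceptors[i])
    }
  }
  locus <- paste0(locus, rand_dna(flank))
  if (strand == "-") {
    L <- nchar(locus)
    locus <- corofam:::revcomp(locus)
    tmp <- L - ex_end
    ex_end <- L - ex_start
    ex_start <- tmp
  }
  new_coro_genes(
    tibble::tibble(gene_id = gene_id, seqid = paste0(gene_id, "_locus"),
                   strand = strand, start = ex_start, end = ex_end),
    stats::setNames(locus, paste0(gene_id, "_locus"))
  )
}

# independent oracle: derive intron position/phase by enumerating the codon
# assignment of every coding nucleotide
oracle_marks <- function(exon_lens) {
  total <- sum(exon_lens)
  codon_of <- ceiling(seq_len(total) / 3)
  bnd <- cumsum(exon_lens)[-length(exon_lens)]
  data.frame(
    intron_index = seq_along(bnd),
    cds_nt_before = bnd,
    residue = vapply(bnd, function(L) {
      if (L %% 3 == 0) L %/% 3 else codon_of[L]
    }, numeric(1)),
    phase = bnd %% 3
  )
}

# independent residue -> column oracle: scan columns counting non-gaps
oracle_res2col <- function(row, residue) {
  chars <- strsplit(row, "")[[1]]
  seen <- 0
  for (j in seq_along(chars)) {
    if (chars[j] != "-") {
      seen <- seen + 1
      if (seen == residue) return(j)
    }
  }
  NA_integer_
}

# regex-based oracle for the motif scanner: overlapping matches per variant
# class via lookahead, best class by rank, leftmost within class
oracle_motif <- function(seq) {
  pats <- c(
    classical = "(?=R[ILVM]..[ILV]E)",
    swapped = "(?=E[ILVM]..[ILV]R)",
    p1_sub = "(?=[^R][ILVM]..[ILV]E)",
    p6_sub = "(?=R[ILVM]..[ILV][^E])",
    `p2/p5_sub` = "(?=R....E)"
  )
  found <- list()
  for (v in names(pats)) {
    m <- gregexpr(pats[[v]], seq, perl = TRUE)[[1]]
    starts <- m[m > 0]
    if (v == "p2/p5_sub" && length(starts)) {
      # exclude windows already matching a hydrophobic-core class
      hyd <- substring(seq, starts + 1, starts + 1) %in% c("I","L","V","M") &
        substring(seq, starts + 4, starts + 4) %in% c("I","L","V")
      starts <- starts[!hyd]
    }
    if (length(starts)) {
      found[[v]] <- min(starts)
    }
  }
  if (length(found) == 0) return(NULL)
  v <- names(found)[1]  # pats ordered by rank
  list(variant = v, start = found[[v]])
}
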