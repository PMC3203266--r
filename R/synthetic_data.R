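# Deterministic, seeded generator of coronin-like protein families with full
# ground truth: class-defining duplication/fusion events, a conserved coronin
# domain, variable unique regions, coiled-coils carrying the trimerization
# motif, exon/intron structures with conserved positions and phases, and
# injectable defects.

# coiled-coil residues outside the motif window avoid R and E so that exactly
# the planted motif window classifies during scanning
CC_ALPHABET <- setdiff(AA20, c("R", "E"))
MOTIF_BASE <- "RIKSLE"  # classical: R-[ILVM]-X-X-[ILV]-E

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

rand_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, p, alphabet = AA20, keep = integer(0)) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  hit <- setdiff(hit, keep)
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- CODONS_BY_AA[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

make_intron <- function(len = 60L, canonical = TRUE) {
  body <- paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE), collapse = "")
  paste0(if (canonical) "GT" else "GC", body, "AG")
}

#' Apply a positional substitution to a motif window
#'
#' @param motif_window A 6-character motif string.
#' @param substitution Named vector/list mapping positions (1-6, as names) to
#'   replacement residues; empty means identity.
#' @return The edited 6-mer.
#' @export
mutate_motif <- function(motif_window, substitution = list()) {
  stopifnot(nchar(motif_window) == 6)
  chars <- strsplit(motif_window, "")[[1]]
  if (length(substitution)) {
    pos <- as.integer(names(substitution))
    res <- toupper(unlist(substitution, use.names = FALSE))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > 6)) abort("motif positions must be 1-6")
    if (!all(res %in% AA20)) abort(sprintf("invalid residue(s): %s", paste(setdiff(res, AA20), collapse = ",")))
    chars[pos] <- res
  }
  paste(chars, collapse = "")
}

VARIANT_SUBS <- list(
  classical = list(),
  p1_K = list(`1` = "K"),
  p1_Q = list(`1` = "Q"),
  p1_A = list(`1` = "A"),
  swapped = list(`1` = "E", `6` = "R"),
  p6_Q = list(`6` = "Q")
)

variant_truth_state <- function(variant) {
  switch(variant,
    classical = "trimer", swapped = "trimer",
    p1_K = "trimer_tetramer_equilibrium",
    p1_A = "tetramer", p1_Q = "tetramer",
    p6_Q = "unknown", "unknown")
}

#' Simulation parameters for a synthetic coronin family
#'
#' Defaults describe the family the analyses target: a ~390-residue conserved
#' coronin domain, a fast-evolving unique region, a 35-residue coiled-coil
#' carrying the trimerization motif, metazoan-specific class-1/class-2
#' duplication, tandem-fusion class-3 genes whose C-terminal domain stays
#' closer to the short-coronin ancestor, villin-fusion class-4 genes, and six
#' conserved intron positions with canonical GT..AG sites.
#'
#' @param seed Integer RNG seed; same parameters give identical output.
#' @param n_species Number of species.
#' @param metazoan_fraction Fraction of species in the metazoan clade (these
#'   get the class-1/class-2 duplication).
#' @param n_class3_species,n_class4_species How many species carry a tandem
#'   class-3 / villin-fusion class-4 gene.
#' @param domain_length Coronin-domain length in residues.
#' @param cc_length Coiled-coil length in residues.
#' @param unique_length_range Range of unique-region lengths (sampled per
#'   sequence from a common template).
#' @param motif_variant_freqs Named frequencies over trimerization-motif
#'   variants (`classical`, `p1_K`, `p1_Q`, `p1_A`, `swapped`, `p6_Q`).
#' @param n_introns Number of conserved intron positions in the coronin
#'   domain.
#' @param intron_length Intron length in nt.
#' @param canonical_prob Probability that a splice site is GT..AG (else
#'   GC..AG).
#' @param class_divergence Substitution probability on the branch from the
#'   short-coronin ancestor to each class ancestor (coronin domain).
#' @param species_divergence Substitution probability from class ancestor to
#'   each leaf (coronin domain).
#' @param unique_rate_multiplier Rate multiplier for the unique region.
#' @param error_model List of planted defects: `n_border_shifts`,
#'   `border_shift_delta` (nt), `n_pseudogenes` (genes receiving
#'   `frameshifts_per_gene` frameshifts and `stops_per_gene` in-frame stops),
#'   and `truncation_fractions` (one truncated gene per entry).
#' @return A `coro_sim_params` list.
#' @export
coro_sim_params <- function(seed = 1L, n_species = 20L, metazoan_fraction = 0.5,
                            n_class3_species = 6L, n_class4_species = 4L,
                            domain_length = 390L, cc_length = 35L,
                            unique_length_range = c(60L, 100L),
                            motif_variant_freqs = c(classical = 0.8, p1_K = 0.05,
                                                    p1_Q = 0.05, swapped = 0.05,
                                                    p6_Q = 0.05),
                            n_introns = 6L, intron_length = 60L,
                            canonical_prob = 1,
                            class_divergence = 0.15, species_divergence = 0.05,
                            unique_rate_multiplier = 3,
                            error_model = list()) {
  em <- utils::modifyList(list(
    n_border_shifts = 0L, border_shift_delta = 4L,
    n_pseudogenes = 0L, frameshifts_per_gene = 2L, stops_per_gene = 1L,
    truncation_fractions = numeric(0)
  ), error_model)
  stopifnot(
    n_species >= 4, metazoan_fraction > 0, metazoan_fraction < 1,
    abs(sum(motif_variant_freqs) - 1) < 1e-9,
    all(names(motif_variant_freqs) %in% names(VARIANT_SUBS)),
    canonical_prob >= 0, canonical_prob <= 1,
    em$border_shift_delta %% 3L != 0L
  )
  structure(list(
    seed = seed, n_species = n_species, metazoan_fraction = metazoan_fraction,
    n_class3_species = n_class3_species, n_class4_species = n_class4_species,
    domain_length = domain_length, cc_length = cc_length,
    unique_length_range = unique_length_range,
    motif_variant_freqs = motif_variant_freqs,
    n_introns = n_introns, intron_length = intron_length,
    canonical_prob = canonical_prob,
    class_divergence = class_divergence, species_divergence = species_divergence,
    unique_rate_multiplier = unique_rate_multiplier,
    error_model = em
  ), class = "coro_sim_params")
}

# split a CDS at cumulative-nt boundaries and interleave introns; returns the
# locus sequence, exon intervals (0-based half-open, plus orientation) and
# the intron site classes used
build_locus <- function(cds, boundaries, intron_length, canonical_prob, flank = 25L) {
  boundaries <- boundaries[boundaries > 0 & boundaries < nchar(cds)]
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, nchar(cds))
  exon_seqs <- substring(cds, starts, ends)
  canonical <- stats::runif(length(boundaries)) < canonical_prob
  introns <- vapply(canonical, function(cn) make_intron(intron_length, cn), character(1))
  flank5 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE), collapse = "")
  locus <- flank5
  ex_start <- integer(0); ex_end <- integer(0)
  for (i in seq_along(exon_seqs)) {
    ex_start[i] <- nchar(locus)
    locus <- paste0(locus, exon_seqs[i])
    ex_end[i] <- nchar(locus)
    if (i <= length(introns)) locus <- paste0(locus, introns[i])
  }
  locus <- paste0(locus, flank3)
  list(locus = locus, start = ex_start, end = ex_end, canonical = canonical)
}

flip_to_minus <- function(locus, start, end) {
  L <- nchar(locus)
  list(locus = revcomp(locus), start = L - end, end = L - start)
}

#' Simulate a coronin-like gene family with ground truth
#'
#' Evolves an ancestral short coronin along a species set: a duplication in
#' the metazoan lineage yields class-1 and class-2; a tandem duplication plus
#' fusion yields class-3 genes whose C-terminal domain stays closer to the
#' short-coronin ancestor than the N-terminal one, terminating in a CA
#' domain; a villin fusion yields class-4 genes with PH, gelsolin and VHP
#' blocks (consumed downstream as annotations). Coiled-coils receive
#' trimerization-motif variants at the requested frequencies; genes receive
#' introns at conserved positions and phases with canonical splice sites; and
#' defects (border shifts, frameshifts, in-frame stops, truncations) are
#' planted per the error model with a full log.
#'
#' @param params A [coro_sim_params()] object.
#' @return A `coro_sim` list: `records` (protein tibble), `full_aln`
#'   (short-coronin alignment), `domain_aln` (all coronin domains, tandem
#'   domains as separate `_Nd`/`_Cd` rows), `genes` (`coro_genes`),
#'   `annotations` (external domain annotations: CC, PH, GEL, VHP, CA),
#'   `species_tree` (`phylo`), and `truth` (per-sequence labels, intron
#'   marks, coiled-coil regions, defect log).
#' @export
simulate_coronin_family <- function(params = coro_sim_params()) {
  stopifnot(inherits(params, "coro_sim_params"))
  with_local_seed(params$seed, {
    p <- params
    species <- sprintf("Sp%02d", seq_len(p$n_species))
    n_met <- max(2L, round(p$n_species * p$metazoan_fraction))
    metazoans <- species[seq_len(n_met)]
    nonmet <- setdiff(species, metazoans)

    # ancestral building blocks
    coro_anc <- rand_aa(p$domain_length)
    unique_anc <- rand_aa(max(p$unique_length_range))
    cc_anc_chars <- strsplit(rand_aa(p$cc_length, CC_ALPHABET), "")[[1]]
    motif_at <- 13L
    cc_anc_chars[motif_at:(motif_at + 5L)] <- strsplit(MOTIF_BASE, "")[[1]]
    cc_anc <- paste(cc_anc_chars, collapse = "")
    c_anc <- "LKSILSQAIHDLVDGLRKHR"       # central region: hydrophobic, basic finish
    a_anc <- "DDEWEDDSDEEFEDA"            # acidic region
    ph_anc <- rand_aa(100L); gel_anc <- rand_aa(80L); vhp_anc <- rand_aa(35L)

    # the metazoan ancestor diverges first, then duplicates into the class-1
    # and class-2 ancestors: class-1 + class-2 are monophyletic while
    # non-metazoan short coronins branch off independently and end up equally
    # related to both classes
    met_anc <- mutate_seq(coro_anc, p$class_divergence)
    class1_dom <- mutate_seq(met_anc, p$class_divergence * 2 / 3)
    class2_dom <- mutate_seq(met_anc, p$class_divergence * 2 / 3)
    class3_Nd <- mutate_seq(coro_anc, p$class_divergence + 0.10)
    class3_Cd <- mutate_seq(coro_anc, p$class_divergence - 0.05)
    class4_dom <- mutate_seq(coro_anc, p$class_divergence + 0.05)

    u_rate <- min(0.9, p$species_divergence * p$unique_rate_multiplier)
    motif_keep <- motif_at:(motif_at + 5L)

    class3_sp <- sample(species, min(p$n_class3_species, p$n_species))
    class4_sp <- sample(species, min(p$n_class4_species, p$n_species))

    # conserved intron boundaries (coding nt before each intron) inside the
    # coronin domain, phases cycling 0/1/2
    res_pos <- round(seq(40, p$domain_length - 40, length.out = p$n_introns))
    phases <- rep(0:2, length.out = p$n_introns)
    intron_cds_nt <- as.integer(3L * res_pos + phases)

    records <- list(); truth <- list(); aln_rows <- list(); dom_rows <- list()
    ann <- list(); gene_models <- list()
    strand_flip <- FALSE

    make_short <- function(id, sp, dom_parent, cls) {
      dom <- mutate_seq(dom_parent, p$species_divergence)
      ulen <- sample(seq(p$unique_length_range[1], p$unique_length_range[2]), 1)
      uniq_full <- mutate_seq(unique_anc, u_rate)
      uniq <- substr(uniq_full, 1, ulen)
      variant <- sample(names(p$motif_variant_freqs), 1, prob = p$motif_variant_freqs)
      cc <- mutate_seq(cc_anc, p$species_divergence, alphabet = CC_ALPHABET,
                       keep = motif_keep)
      motif <- mutate_motif(substr(cc, motif_at, motif_at + 5L), VARIANT_SUBS[[variant]])
      cc <- paste0(substr(cc, 1, motif_at - 1L), motif,
                   substr(cc, motif_at + 6L, nchar(cc)))
      prot <- paste0(dom, uniq, cc)
      cc_start <- p$domain_length + ulen + 1L
      aln_row <- paste0(dom, uniq,
                        strrep("-", max(p$unique_length_range) - ulen), cc)
      list(id = id, species = sp, protein = prot, class = cls, variant = variant,
         oligomer = variant_truth_state(variant), dom = dom, aln_row = aln_row,
         cc_region = c(cc_start, cc_start + nchar(cc) - 1L))
    }

    for (sp in species) {
      if (sp %in% metazoans) {
        for (k in 1:2) {
          g <- make_short(sprintf("%sCoro%d", sp, k), sp,
                          if (k == 1) class1_dom else class2_dom,
                          sprintf("class-%d", k))
          records[[g$id]] <- g
        }
      } else {
        # each non-metazoan lineage diverges independently from the ancestor
        lineage <- mutate_seq(coro_anc, p$class_divergence)
        g <- make_short(paste0(sp, "Coro"), sp, lineage, "unclassified")
        records[[g$id]] <- g
      }
    }
    for (sp in class3_sp) {
      id <- paste0(sp, "Coro3")
      nd <- mutate_seq(class3_Nd, p$species_divergence)
      cd <- mutate_seq(class3_Cd, p$species_divergence)
      linker1 <- rand_aa(25L); linker2 <- rand_aa(25L)
      ca_linker <- rand_aa(8L)
      c_reg <- mutate_seq(c_anc, p$species_divergence)
      a_reg <- mutate_seq(a_anc, p$species_divergence)
      prot <- paste0(nd, linker1, cd, linker2, c_reg, ca_linker, a_reg)
      records[[id]] <- list(id = id, species = sp, protein = prot,
                            class = "class-3", variant = NA_character_,
                            oligomer = "no_coiled_coil", dom = NULL,
                            nd = nd, cd = cd, c_reg = c_reg, a_reg = a_reg,
                            aln_row = NULL, cc_region = NULL)
    }
    for (sp in class4_sp) {
      id <- paste0(sp, "Coro4")
      dom <- mutate_seq(class4_dom, p$species_divergence)
      n_ph <- sample(3:4, 1); n_gel <- sample(4:5, 1)
      blocks <- c(
        replicate(n_ph, mutate_seq(ph_anc, p$species_divergence)),
        replicate(n_gel, mutate_seq(gel_anc, p$species_divergence)),
        mutate_seq(vhp_anc, p$species_divergence)
      )
      prot <- paste0(dom, rand_aa(20L), paste(blocks, collapse = ""))
      # external annotations for the villin-derived blocks
      pos <- p$domain_length + 20L
      names_blocks <- c(rep("PH", n_ph), rep("GEL", n_gel), "VHP")
      lens <- nchar(blocks)
      for (b in seq_along(blocks)) {
        ann[[length(ann) + 1L]] <- tibble(
          seq_id = id, domain_name = names_blocks[b],
          start = pos + 1L, end = pos + lens[b], score = 100,
          source = "annotation")
        pos <- pos + lens[b]
      }
      records[[id]] <- list(id = id, species = sp, protein = prot,
                            class = "class-4", variant = NA_character_,
                            oligomer = "no_coiled_coil", dom = dom,
                            aln_row = NULL, cc_region = NULL)
    }

    # coiled-coil annotations for short coronins
    for (g in records) {
      if (!is.null(g$cc_region)) {
        ann[[length(ann) + 1L]] <- tibble(
          seq_id = g$id, domain_name = "CC",
          start = g$cc_region[1], end = g$cc_region[2], score = 100,
          source = "annotation")
      }
    }

    # gene structures: back-translate and insert conserved introns
    exon_tbl <- list(); genomic <- character(0)
    true_marks <- list(); splice_truth <- list()
    for (g in records) {
      cds <- back_translate(g$protein)
      bnd <- intron_cds_nt[intron_cds_nt < nchar(cds) - 3L]
      loc <- build_locus(cds, bnd, p$intron_length, p$canonical_prob)
      strand <- if (strand_flip) "-" else "+"
      strand_flip <- !strand_flip
      seqid <- paste0(g$id, "_locus")
      if (strand == "-") {
        fl <- flip_to_minus(loc$locus, loc$start, loc$end)
        genomic[[seqid]] <- fl$locus
        st <- rev(fl$start); en <- rev(fl$end)   # genomic order after flip
        exon_tbl[[g$id]] <- tibble(gene_id = g$id, seqid = seqid, strand = strand,
                                   start = sort(st), end = sort(en))
      } else {
        genomic[[seqid]] <- loc$locus
        exon_tbl[[g$id]] <- tibble(gene_id = g$id, seqid = seqid, strand = strand,
                                   start = loc$start, end = loc$end)
      }
      if (length(bnd)) {
        true_marks[[g$id]] <- tibble(
          gene_id = g$id, intron_index = seq_along(bnd),
          cds_nt_before = bnd, residue = as.integer(ceiling(bnd / 3)),
          phase = as.integer(bnd %% 3L))
        splice_truth[[g$id]] <- tibble(
          gene_id = g$id, intron_index = seq_along(bnd),
          status = ifelse(loc$canonical, "canonical", "noncanonical"))
      }
    }
    genes <- new_coro_genes(bind_rows(exon_tbl), genomic)

    fld <- function(name) unname(map_chr(records, name))
    rec_tbl <- tibble(
      id = fld("id"),
      species = fld("species"),
      protein = fld("protein"),
      class_label = NA_character_,
      completeness = NA_character_,
      pseudogene = NA
    )
    truth_tbl <- tibble(
      id = fld("id"),
      species = fld("species"),
      class = fld("class"),
      motif_variant = fld("variant"),
      oligomer_state = fld("oligomer"),
      full_length = nchar(fld("protein")),
      completeness = "Complete",
      pseudogene = FALSE
    )

    full_aln <- bind_rows(map(records, function(g) {
      if (is.null(g$aln_row)) return(NULL)
      tibble(id = g$id, seq = g$aln_row)
    }))
    domain_aln <- bind_rows(map(records, function(g) {
      if (g$class == "class-3") {
        tibble(id = paste0(g$id, c("_Nd", "_Cd")), seq = c(g$nd, g$cd))
      } else {
        tibble(id = g$id, seq = g$dom)
      }
    }))

    # CA-region alignments (class-3 rows), the inputs for the C/A profiles
    ca_c_aln <- bind_rows(map(records, function(g) {
      if (g$class != "class-3") return(NULL)
      tibble(id = g$id, seq = g$c_reg)
    }))
    ca_a_aln <- bind_rows(map(records, function(g) {
      if (g$class != "class-3") return(NULL)
      tibble(id = g$id, seq = g$a_reg)
    }))

    cc_regions <- bind_rows(map(records, function(g) {
      if (is.null(g$cc_region)) return(NULL)
      tibble(seq_id = g$id, start = g$cc_region[1], end = g$cc_region[2])
    }))

    # species tree: metazoan clade vs the rest, ladders inside
    ladder <- function(x) {
      if (length(x) == 1) return(x)
      Reduce(function(a, b) sprintf("(%s:1,%s:1):1", a, b), x)
    }
    nwk <- sprintf("(%s:1,%s:1);", ladder(metazoans), ladder(nonmet))
    species_tree <- ape::read.tree(text = nwk)

    defect_log <- tibble(gene_id = character(0), type = character(0),
                         detail = character(0))

    # --- planted defects -------------------------------------------------
    em <- p$error_model
    short_ids <- truth_tbl$id[truth_tbl$class %in% c("class-1", "class-2", "unclassified")]
    avail <- short_ids

    if (em$n_border_shifts > 0) {
      targets <- sample(avail, em$n_border_shifts)
      avail <- setdiff(avail, targets)
      for (g in targets) {
        k <- sample(seq_len(nrow(true_marks[[g]])), 1)
        genes <- slide_intron(genes, g, k, em$border_shift_delta)
        defect_log <- bind_rows(defect_log, tibble(
          gene_id = g, type = "border_shift",
          detail = sprintf("intron %d slid by %+d nt", k, em$border_shift_delta)))
      }
    }

    if (em$n_pseudogenes > 0) {
      targets <- sample(avail, em$n_pseudogenes)
      avail <- setdiff(avail, targets)
      for (g in targets) {
        ex <- gene_exons(genes, g)
        for (f in seq_len(em$frameshifts_per_gene)) {
          j <- sample(nrow(ex) - 1L, 1)  # not the last exon
          genes <- plant_frameshift(genes, g, j)
          defect_log <- bind_rows(defect_log, tibble(
            gene_id = g, type = "frameshift",
            detail = sprintf("1 nt deleted in exon %d", j)))
        }
        for (s in seq_len(em$stops_per_gene)) {
          codon <- sample(10:30, 1)  # within the first exon of every gene
          genes <- plant_internal_stop(genes, g, codon)
          defect_log <- bind_rows(defect_log, tibble(
            gene_id = g, type = "internal_stop",
            detail = sprintf("TAA at codon %d", codon)))
        }
        lesions <- em$frameshifts_per_gene + em$stops_per_gene
        truth_tbl$pseudogene[truth_tbl$id == g] <- lesions >= 3
      }
    }

    if (length(em$truncation_fractions) > 0) {
      targets <- sample(avail, length(em$truncation_fractions))
      for (t in seq_along(targets)) {
        g <- targets[t]; frac <- em$truncation_fractions[t]
        full <- rec_tbl$protein[rec_tbl$id == g]
        keep <- floor(nchar(full) * (1 - frac))
        rec_tbl$protein[rec_tbl$id == g] <- substr(full, 1, keep)
        genes <- truncate_gene(genes, g, keep_nt = 3L * keep)
        row <- full_aln$seq[full_aln$id == g]
        chars <- strsplit(row, "")[[1]]
        nong <- which(chars != "-")
        if (keep < length(nong)) chars[nong[(keep + 1):length(nong)]] <- "-"
        full_aln$seq[full_aln$id == g] <- paste(chars, collapse = "")
        mf <- 1 - keep / nchar(full)
        truth_tbl$completeness[truth_tbl$id == g] <-
          if (mf == 0) "Complete" else if (mf <= 0.05) "Partial" else "Fragment"
        true_marks[[g]] <- true_marks[[g]][true_marks[[g]]$cds_nt_before < 3L * keep, ]
        defect_log <- bind_rows(defect_log, tibble(
          gene_id = g, type = "truncation",
          detail = sprintf("kept %d of %d residues", keep, nchar(full))))
      }
    }

    structure(list(
      records = rec_tbl,
      full_aln = full_aln,
      domain_aln = domain_aln,
      ca_c_aln = ca_c_aln,
      ca_a_aln = ca_a_aln,
      genes = genes,
      annotations = bind_rows(ann),
      species_tree = species_tree,
      truth = list(
        labels = truth_tbl,
        intron_marks = bind_rows(true_marks),
        splice_status = bind_rows(splice_truth),
        cc_regions = cc_regions,
        expected_phases = bind_rows(true_marks)[c("gene_id", "intron_index", "phase")],
        defects = defect_log
      ),
      params = p
    ), class = "coro_sim")
  })
}

#' @export
print.coro_sim <- function(x, ...) {
  cat(sprintf("<coro_sim> %d records, %d species, seed %d\n",
              nrow(x$records), length(unique(x$records$species)), x$params$seed))
  invisible(x)
}

# --- structural corruption helpers -------------------------------------

# map a transcript CDS coordinate (1-based nt) to a genomic 0-based position
cds_to_genomic <- function(genes, gene_id, cds_pos) {
  ex <- gene_exons(genes, gene_id)
  len <- ex$end - ex$start
  cum <- cumsum(len)
  j <- which(cds_pos <= cum)[1]
  off <- cds_pos - c(0L, cum)[j] - 1L  # 0-based offset within exon j
  if (ex$strand[1] == "+") ex$start[j] + off else ex$end[j] - 1L - off
}

#' Slide an intron along the genome
#'
#' Moves both the donor and the acceptor of intron `intron_index`
#' (transcript order) by `delta` nt downstream in transcript orientation, so
#' the flanking exon borders shift but the total CDS length is preserved;
#' only the slid intron's position/phase mark changes.
#'
#' @param genes A `coro_genes` object.
#' @param gene_id Gene to modify.
#' @param intron_index Intron to slide (1-based, 5' to 3').
#' @param delta Shift in nt (positive = downstream).
#' @return The modified `coro_genes`.
#' @export
slide_intron <- function(genes, gene_id, intron_index, delta) {
  ex <- gene_exons(genes, gene_id)
  stopifnot(intron_index >= 1, intron_index < nrow(ex))
  i <- intron_index
  rows <- which(genes$exons$gene_id == gene_id)
  exr <- genes$exons[rows, ]
  if (ex$strand[1] == "+") {
    exr$end[exr$exon == i] <- exr$end[exr$exon == i] + delta
    exr$start[exr$exon == i + 1] <- exr$start[exr$exon == i + 1] + delta
  } else {
    exr$start[exr$exon == i] <- exr$start[exr$exon == i] - delta
    exr$end[exr$exon == i + 1] <- exr$end[exr$exon == i + 1] - delta
  }
  genes$exons[rows, ] <- exr
  genes
}

#' Plant a 1-nt frameshift in an exon
#'
#' Deletes one nucleotide inside the given exon (transcript order), shifting
#' the reading frame of everything downstream.
#'
#' @param genes A `coro_genes` object.
#' @param gene_id Gene to modify.
#' @param exon_index Exon (transcript order) receiving the deletion.
#' @return The modified `coro_genes`.
#' @export
plant_frameshift <- function(genes, gene_id, exon_index) {
  ex <- gene_exons(genes, gene_id)
  stopifnot(exon_index >= 1, exon_index <= nrow(ex))
  seqid <- ex$seqid[1]
  target <- ex[ex$exon == exon_index, ]
  pos <- target$start + (target$end - target$start) %/% 2L  # 0-based genomic
  sq <- genes$genomic[[seqid]]
  genes$genomic[[seqid]] <- paste0(substr(sq, 1, pos), substr(sq, pos + 2L, nchar(sq)))
  rows <- which(genes$exons$gene_id == gene_id & genes$exons$seqid == seqid)
  exr <- genes$exons[rows, ]
  exr$end[exr$end > pos] <- exr$end[exr$end > pos] - 1L
  exr$start[exr$start > pos] <- exr$start[exr$start > pos] - 1L
  genes$exons[rows, ] <- exr
  genes
}

#' Plant an in-frame stop codon
#'
#' Overwrites codon `codon_index` of the spliced CDS with TAA (in transcript
#' orientation; the genomic write respects strand). The codon must lie
#' entirely within one exon.
#'
#' @param genes A `coro_genes` object.
#' @param gene_id Gene to modify.
#' @param codon_index 1-based codon in the spliced CDS.
#' @return The modified `coro_genes`.
#' @export
plant_internal_stop <- function(genes, gene_id, codon_index) {
  ex <- gene_exons(genes, gene_id)
  seqid <- ex$seqid[1]
  cds_pos <- 3L * (codon_index - 1L) + 1L
  g1 <- cds_to_genomic(genes, gene_id, cds_pos)
  g3 <- cds_to_genomic(genes, gene_id, cds_pos + 2L)
  sq <- genes$genomic[[seqid]]
  if (ex$strand[1] == "+") {
    stopifnot(g3 == g1 + 2L)  # within one exon
    substr(sq, g1 + 1L, g1 + 3L) <- "TAA"
  } else {
    stopifnot(g3 == g1 - 2L)
    substr(sq, g3 + 1L, g3 + 3L) <- "TTA"  # revcomp(TAA)
  }
  genes$genomic[[seqid]] <- sq
  genes
}

#' Truncate a gene structure to its first `keep_nt` coding nucleotides
#'
#' @param genes A `coro_genes` object.
#' @param gene_id Gene to truncate.
#' @param keep_nt Coding nucleotides to keep (from the 5' end).
#' @return The modified `coro_genes`.
#' @export
truncate_gene <- function(genes, gene_id, keep_nt) {
  ex <- gene_exons(genes, gene_id)
  len <- ex$end - ex$start
  cum <- cumsum(len)
  keep_ex <- which(c(0L, cum)[seq_len(nrow(ex))] < keep_nt)
  rows <- which(genes$exons$gene_id == gene_id)
  exr <- genes$exons[rows, ]
  drop <- !exr$exon %in% keep_ex
  last <- max(keep_ex)
  excess <- cum[last] - keep_nt
  if (excess > 0) {
    if (ex$strand[1] == "+") {
      exr$end[exr$exon == last] <- exr$end[exr$exon == last] - excess
    } else {
      exr$start[exr$exon == last] <- exr$start[exr$exon == last] + excess
    }
  }
  genes$exons <- bind_rows(genes$exons[-rows, ], exr[!drop, ])
  genes
}

mutate_nt <- function(s, p) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Plant a duplicated (mutually-exclusive-style) internal exon
#'
#' Duplicates exon `exon_index` of a gene: the copy is diverged at the
#' nucleotide level, inserted immediately downstream behind a new canonical
#' intron, and downstream exon coordinates shift. Because the copy keeps the
#' original length, the duplicated pair shares an identical splice phase
#' context — the signature the detector keys on.
#'
#' @param genes A `coro_genes` object.
#' @param gene_id Gene to modify.
#' @param exon_index Internal exon (transcript order) to duplicate.
#' @param divergence Per-nucleotide substitution probability for the copy.
#' @param intron_length Length of the inserted intron.
#' @param seed RNG seed.
#' @return A list: `genes` (modified) and `cluster` (ground-truth tibble with
#'   the duplicated pair's exon indices and realized translated identity).
#' @export
plant_mxe <- function(genes, gene_id, exon_index, divergence = 0.05,
                      intron_length = 60L, seed = 1L) {
  with_local_seed(seed, {
    ex <- gene_exons(genes, gene_id)
    stopifnot(exon_index > 1, exon_index < nrow(ex))
    len <- ex$end - ex$start
    cum_before <- c(0L, cumsum(len))[exon_index]
    up_phase <- as.integer(cum_before %% 3L)
    seqs <- exon_sequences(genes, gene_id)
    dup_nt <- mutate_nt(seqs[exon_index], divergence)
    aa <- translate_in_phase(seqs[exon_index], up_phase)
    aa2 <- translate_in_phase(dup_nt, up_phase)
    intron <- make_intron(intron_length, TRUE)
    insert <- paste0(intron, dup_nt)
    seqid <- ex$seqid[1]
    sq <- genes$genomic[[seqid]]
    plus <- ex$strand[1] == "+"
    # insertion point: transcript end of exon `exon_index`
    if (plus) {
      at <- ex$end[exon_index]  # 0-based: insert after this point
      genes$genomic[[seqid]] <- paste0(substr(sq, 1, at), insert,
                                       substr(sq, at + 1L, nchar(sq)))
      shift <- nchar(insert)
      rows <- which(genes$exons$gene_id == gene_id)
      exr <- genes$exons[rows, ]
      exr$start[exr$start >= at] <- exr$start[exr$start >= at] + shift
      exr$end[exr$end > at] <- exr$end[exr$end > at] + shift
      new_exon <- tibble(gene_id = gene_id, seqid = seqid, strand = "+",
                         start = at + nchar(intron),
                         end = at + nchar(intron) + nchar(dup_nt))
      genes$exons <- bind_rows(genes$exons[-rows, ], exr, new_exon)
    } else {
      at <- ex$start[exon_index]  # transcript-downstream end in genomic coords
      insert_rc <- revcomp(insert)
      genes$genomic[[seqid]] <- paste0(substr(sq, 1, at), insert_rc,
                                       substr(sq, at + 1L, nchar(sq)))
      shift <- nchar(insert)
      rows <- which(genes$exons$gene_id == gene_id)
      exr <- genes$exons[rows, ]
      exr$start[exr$start >= at] <- exr$start[exr$start >= at] + shift
      exr$end[exr$end > at] <- exr$end[exr$end > at] + shift
      new_exon <- tibble(gene_id = gene_id, seqid = seqid, strand = "-",
                         start = at, end = at + nchar(dup_nt))
      genes$exons <- bind_rows(genes$exons[-rows, ], exr, new_exon)
    }
    genes2 <- new_coro_genes(genes$exons, genes$genomic)
    list(
      genes = genes2,
      cluster = tibble(gene_id = gene_id, exon_from = exon_index,
                       exon_to = exon_index + 1L,
                       identity_planted = ungapped_identity(aa, aa2))
    )
  })
}

#' Corrupt gene structures according to an error model
#'
#' Randomized wrapper over [slide_intron()], [plant_frameshift()] and
#' [plant_internal_stop()]: samples target genes and plants the requested
#' number of defects, returning the modified structures and a log sufficient
#' to verify downstream detection.
#'
#' @param genes A `coro_genes` object.
#' @param error_model List with any of `n_border_shifts`,
#'   `border_shift_delta`, `n_frameshifts`, `n_stops`, `same_gene` (put all
#'   frameshifts/stops on one gene).
#' @param seed RNG seed.
#' @return A list: `genes` (modified) and `log` (tibble `gene_id`, `type`,
#'   `detail`).
#' @export
corrupt_gene_structure <- function(genes, error_model = list(), seed = 1L) {
  em <- utils::modifyList(list(n_border_shifts = 0L, border_shift_delta = 4L,
                               n_frameshifts = 0L, n_stops = 0L,
                               same_gene = FALSE), error_model)
  with_local_seed(seed, {
    log <- tibble(gene_id = character(0), type = character(0), detail = character(0))
    multi <- genes$exons |> count(.data$gene_id) |> filter(.data$n >= 2) |> pull(.data$gene_id)
    if (em$n_border_shifts > 0) {
      targets <- sample(multi, em$n_border_shifts)
      for (g in targets) {
        k <- sample(sum(genes$exons$gene_id == g) - 1L, 1)
        genes <- slide_intron(genes, g, k, em$border_shift_delta)
        log <- bind_rows(log, tibble(gene_id = g, type = "border_shift",
                                     detail = sprintf("intron %d by %+d nt", k, em$border_shift_delta)))
      }
    }
    n_lesion_genes <- if (em$same_gene) 1L else max(em$n_frameshifts, em$n_stops)
    if (em$n_frameshifts > 0 || em$n_stops > 0) {
      targets <- sample(multi, n_lesion_genes)
      fs_targets <- rep(targets, length.out = em$n_frameshifts)
      st_targets <- rep(targets, length.out = em$n_stops)
      for (g in fs_targets) {
        j <- sample(sum(genes$exons$gene_id == g) - 1L, 1)
        genes <- plant_frameshift(genes, g, j)
        log <- bind_rows(log, tibble(gene_id = g, type = "frameshift",
                                     detail = sprintf("exon %d", j)))
      }
      for (g in st_targets) {
        codon <- sample(10:30, 1)
        genes <- plant_internal_stop(genes, g, codon)
        log <- bind_rows(log, tibble(gene_id = g, type = "internal_stop",
                                     detail = sprintf("codon %d", codon)))
      }
    }
    list(genes = genes, log = log)
  })
}
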