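test_that("intron positions and phases match codon enumeration on toy CDSs", {
  # spec'd toy cases
  g1 <- toy_genes(c(9, 9))
  m1 <- intron_marks(g1)
  expect_equal(m1$cds_nt_before, 9L)
  expect_equal(m1$residue, 3L)
  expect_equal(m1$phase, 0L)

  g2 <- toy_genes(c(10, 8))
  m2 <- intron_marks(g2)
  expect_equal(m2$cds_nt_before, 10L)
  expect_equal(m2$residue, 4L)
  expect_equal(m2$phase, 1L)

  expect_equal(nrow(intron_marks(toy_genes(30))), 0)

  # property: agreement with the nucleotide-walk oracle on random exon models,
  # both strands
  set.seed(21)
  for (i in 1:25) {
    lens <- sample(5:40, sample(2:6, 1), replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    g <- toy_genes(lens, strand = strand)
    got <- intron_marks(g)
    exp <- oracle_marks(lens)
    expect_equal(got$cds_nt_before, exp$cds_nt_before)
    expect_equal(got$residue, as.integer(exp$residue))
    expect_equal(got$phase, as.integer(exp$phase))
  }
})

test_that("phase equals cumulative CDS length mod 3 at every boundary", {
  set.seed(77)
  for (i in 1:10) {
    lens <- sample(6:50, 5, replace = TRUE)
    g <- toy_genes(lens, strand = sample(c("+", "-"), 1))
    m <- intron_marks(g)
    expect_equal(m$phase, m$cds_nt_before %% 3L)
    expect_equal(m$residue, as.integer(ceiling(m$cds_nt_before / 3)))
  }
})

test_that("splice-site rule table: GT..AG canonical, GC..AG / AT..AC noncanonical, else violation", {
  g <- toy_genes(c(9, 9, 9, 9), donors = c("GT", "GC", "AT"),
                 acceptors = c("AG", "AG", "AC"))
  s <- validate_splice_sites(g)
  expect_equal(s$status, c("canonical", "noncanonical", "noncanonical"))

  g2 <- toy_genes(c(9, 9), donors = "CT", acceptors = "AG")
  expect_equal(validate_splice_sites(g2)$status, "violation")

  # planted GT..AG introns on the minus strand are still read as canonical
  g3 <- toy_genes(c(12, 9, 6, 9, 12, 9), strand = "-")
  expect_equal(validate_splice_sites(g3)$status, rep("canonical", 5))
})

test_that("intron projection maps residues to alignment columns and round-trips", {
  marks <- tibble::tibble(gene_id = "r1", intron_index = 1:2,
                          cds_nt_before = c(9L, 16L), residue = c(3L, 6L),
                          phase = c(0L, 1L))
  aln <- tibble::tibble(id = "r1", seq = "MK-VLD")
  # ungapped row: column == residue
  p0 <- project_introns(tibble::tibble(id = "r1", seq = "MKVLDPEW"), marks[1, ])
  expect_equal(p0$column, 3L)
  # "MK-VLD", residue 3 (V) sits in column 4
  p1 <- project_introns(aln, marks[1, ])
  expect_equal(p1$column, 4L)
  expect_error(project_introns(aln, marks[2, ]), "beyond")

  # identical rows with identical structures give identical (column, phase)
  aln2 <- tibble::tibble(id = c("a", "b"), seq = rep("MK-VLD--PEW", 2))
  mk <- tibble::tibble(gene_id = c("a", "b"), intron_index = 1L,
                       cds_nt_before = 12L, residue = 4L, phase = 0L)
  p2 <- project_introns(aln2, mk)
  expect_equal(p2$column[1], p2$column[2])

  # property: projection agrees with a column-scan oracle and round-trips
  set.seed(31)
  for (i in 1:20) {
    chars <- sample(c(AA20_T, "-"), 40, replace = TRUE, prob = c(rep(1, 20), 8))
    row <- paste(chars, collapse = "")
    n_res <- sum(chars != "-")
    if (n_res == 0) next
    res <- sample(n_res, 1)
    col <- residue_to_column(row, res)
    expect_equal(col, oracle_res2col(row, res))
    expect_equal(column_to_residue(row, col), res)
  }
})

test_that("border flagging counts homolog support within the window", {
  # 5 genes sharing a phase-0 intron at column 40: all supported
  mk <- tibble::tibble(gene_id = paste0("g", 1:5), intron_index = 1L,
                       cds_nt_before = 120L, residue = 40L, phase = 0L,
                       column = c(40L, 40L, 41L, 39L, 40L))
  fl <- flag_borders(mk, min_support = 2)
  expect_true(all(fl$verdict == "supported"))
  expect_true(all(fl$n_support == 4))

  # a unique phase-1 intron is suspicious even at min_support = 1
  mk2 <- dplyr::bind_rows(mk, tibble::tibble(
    gene_id = "g6", intron_index = 1L, cds_nt_before = 121L,
    residue = 41L, phase = 1L, column = 40L))
  fl2 <- flag_borders(mk2, min_support = 1)
  expect_equal(fl2$verdict[fl2$gene_id == "g6"], "suspicious")
  expect_true(all(fl2$verdict[fl2$gene_id != "g6"] == "supported"))
})

test_that("mutually exclusive exon detection finds planted duplications only", {
  set.seed(5)
  # planted duplication: same-length internal exon copy, high identity
  base <- toy_genes(c(30, 36, 36, 30), gene_id = "mxe")
  # make exons 2 and 3 near-identical at the nt level
  ex <- base$exons
  sq <- base$genomic[[1]]
  e2 <- substr(sq, ex$start[2] + 1, ex$end[2])
  e3_mut <- corofam:::mutate_nt(e2, 0.05)
  substr(sq, ex$start[3] + 1, ex$end[3]) <- e3_mut
  genes <- new_coro_genes(ex, stats::setNames(sq, names(base$genomic)))
  got <- detect_mxe(genes, min_identity = 0.3)
  expect_equal(nrow(got), 1)
  expect_equal(got$exon_from, 2L)
  expect_equal(got$exon_to, 3L)
  expect_gte(got$pairwise_identity, 0.3)

  # no similar pair: nothing reported
  expect_equal(nrow(detect_mxe(toy_genes(c(30, 36, 45, 30)))), 0)

  # same content but mismatched phase context (lengths differ mod 3): rejected
  base2 <- toy_genes(c(30, 36, 35, 30), gene_id = "ctx")
  ex2 <- base2$exons
  sq2 <- base2$genomic[[1]]
  donor <- substr(sq2, ex2$start[2] + 1, ex2$end[2])
  substr(sq2, ex2$start[3] + 1, ex2$end[3]) <- substr(donor, 1, 35)
  genes2 <- new_coro_genes(ex2, stats::setNames(sq2, names(base2$genomic)))
  expect_equal(nrow(detect_mxe(genes2, min_identity = 0.3)), 0)
})

test_that("completeness categories follow the 5% partial rule", {
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         protein = c(rand_prot(400), rand_prot(390),
                                     rand_prot(300)))
  cc <- call_completeness(recs, 400)
  expect_equal(cc$completeness, c("Complete", "Partial", "Fragment"))
  expect_equal(cc$missing_fraction, c(0, 0.025, 0.25), tolerance = 1e-12)
  # exactly 5% missing is still Partial
  cc5 <- call_completeness(tibble::tibble(id = "e", protein = rand_prot(380)), 400)
  expect_equal(cc5$completeness, "Partial")
  # a record longer than expected: never negative missingness
  cc_long <- call_completeness(tibble::tibble(id = "f", protein = rand_prot(420)), 400)
  expect_equal(cc_long$missing_fraction, 0)
})

test_that("pseudogene calls require enough lesions or lesions plus missing sequence", {
  # clean gene: no lesions, verdict FALSE
  prot <- rand_prot(60, seed = 12)
  cds <- corofam:::with_local_seed(1, corofam:::back_translate(prot))
  g <- toy_genes(c(60, 60, 60), cds = cds)
  exp_ph <- intron_marks(g)[c("gene_id", "intron_index", "phase")]
  ps <- call_pseudogene(g, expected_phases = exp_ph)
  expect_false(ps$pseudogene)
  expect_equal(ps$n_frameshifts + ps$n_internal_stops, 0L)

  # single internal stop stays below the default threshold
  g1 <- plant_internal_stop(g, "g1", codon_index = 10)
  ps1 <- call_pseudogene(g1, expected_phases = exp_ph)
  expect_equal(ps1$n_internal_stops, 1L)
  expect_false(ps1$pseudogene)

  # 2 frameshifts + 1 stop reach the default threshold of 3
  g2 <- plant_frameshift(g, "g1", 1)
  g2 <- plant_frameshift(g2, "g1", 2)
  g2 <- plant_internal_stop(g2, "g1", 5)
  ps2 <- call_pseudogene(g2, expected_phases = exp_ph)
  expect_gte(ps2$n_frameshifts + ps2$n_internal_stops, 3)
  expect_equal(ps2$n_frameshifts, 2L)
  expect_true(ps2$pseudogene)

  # one lesion plus >20% missing sequence also flips the verdict
  ps3 <- call_pseudogene(g1, expected_phases = exp_ph,
                         missing_fraction = c(g1 = 0.3))
  expect_true(ps3$pseudogene)
})
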