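test_that("PSSM scores match closed forms", {
  # invariant column of R, vanishing pseudocount: score(R) = log2(20)
  aln <- tibble::tibble(id = paste0("r", 1:10), seq = rep("R", 10))
  p <- build_pssm(aln, pseudocount = 0)
  expect_equal(unname(p["R", 1]), log2(20), tolerance = 1e-12)
  expect_true(all(p[setdiff(rownames(p), "R"), 1] == attr(p, "cap")))

  # uniform column: every score 0
  aln_u <- tibble::tibble(id = paste0("r", 1:20), seq = AA20_T)
  p_u <- build_pssm(aln_u, pseudocount = 0)
  expect_equal(unname(p_u[, 1]), rep(0, 20), tolerance = 1e-12)

  # 50/50 R/K column: both log2(10)
  aln_rk <- tibble::tibble(id = paste0("r", 1:10), seq = rep(c("R", "K"), 5))
  p_rk <- build_pssm(aln_rk, pseudocount = 0)
  expect_equal(unname(p_rk["R", 1]), log2(10), tolerance = 1e-12)
  expect_equal(unname(p_rk["K", 1]), log2(10), tolerance = 1e-12)

  # gap cells excluded from counts; all-gap column errors
  aln_g <- tibble::tibble(id = c("a", "b", "c"), seq = c("R-", "R-", "--"))
  expect_error(build_pssm(aln_g), "all-gap")
  p_g <- build_pssm(aln_g, columns = 1, pseudocount = 0)
  expect_equal(unname(p_g["R", 1]), log2(20), tolerance = 1e-12)
})

test_that("domain scanning finds planted profile instances and nothing in noise", {
  set.seed(42)
  aln <- tibble::tibble(id = paste0("r", 1:12),
                        seq = replicate(12, corofam:::mutate_seq(rand_prot(50), 0.1)))
  p <- build_pssm(aln)
  cons <- pssm_consensus(p)

  # consensus score attains the column-max upper bound
  hit <- scan_domain(cons, p)
  expect_equal(hit$score, glance(p)$max_score, tolerance = 1e-9)

  # planted at a known offset inside random flanks
  seq1 <- paste0(rand_prot(37), cons, rand_prot(23))
  h1 <- scan_domain(tibble::tibble(id = "q", protein = seq1), p)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, 38L)
  expect_equal(h1$end, 37L + 50L)

  # tandem instances give two non-overlapping hits
  seq2 <- paste0(rand_prot(10), cons, rand_prot(25), cons, rand_prot(10))
  h2 <- scan_domain(tibble::tibble(id = "t", protein = seq2), p)
  expect_equal(nrow(h2), 2)
  expect_true(h2$start[2] > h2$end[1])

  # random sequences score below the default threshold
  noise <- tibble::tibble(id = paste0("n", 1:200),
                          protein = replicate(200, rand_prot(120)))
  expect_equal(nrow(scan_domain(noise, p)), 0)
})

test_that("trimerization motif windows classify into the documented variants", {
  expect_equal(classify_motif("RLASLE")$variant, "classical")
  expect_equal(classify_motif("RIKSVE")$variant, "classical")
  q <- classify_motif("QLASLE")
  expect_equal(q$variant, "p1_sub"); expect_equal(q$detail, "Q")
  expect_equal(classify_motif("ELASLR")$variant, "swapped")
  p6 <- classify_motif("RIKSVQ")
  expect_equal(p6$variant, "p6_sub"); expect_equal(p6$detail, "Q")
  expect_equal(classify_motif("RPKSPE")$variant, "p2/p5_sub")
  expect_equal(classify_motif("GGGGGG")$variant, "none")
})

test_that("motif scanning prefers the best variant class and the leftmost tie", {
  recs <- tibble::tibble(id = "s1", protein = paste0("GG", "QLASLE", "GG", "RLASLE", "GG"))
  cc <- tibble::tibble(seq_id = "s1", start = 1L, end = nchar(recs$protein))
  hit <- find_trimerization_motif(recs, cc_regions = cc)
  expect_equal(hit$variant, "classical")  # classical outranks the earlier p1_sub
  expect_equal(hit$start, 11L)

  recs2 <- tibble::tibble(id = "s2", protein = paste0("G", "RLASLE", "GG", "RIKSVE", "G"))
  cc2 <- tibble::tibble(seq_id = "s2", start = 1L, end = nchar(recs2$protein))
  hit2 <- find_trimerization_motif(recs2, cc_regions = cc2)
  expect_equal(hit2$start, 2L)  # leftmost classical wins the tie

  # without annotation only the C-terminal window is scanned
  recs3 <- tibble::tibble(id = "s3", protein = paste0("RLASLE", rand_prot(80, seed = 3)))
  hit3 <- find_trimerization_motif(recs3, tail_window = 60)
  expect_true(nrow(hit3) == 0 || hit3$start > 6)
})

test_that("oligomer prediction follows the substitution rule table", {
  mk <- function(res, variant, detail = NA_character_) {
    tibble::tibble(seq_id = "x", start = 1L, residues = res,
                   variant = variant, detail = detail)
  }
  expect_equal(predict_oligomer("x", mk("RIKSVE", "classical"))$state, "trimer")
  expect_equal(predict_oligomer("x", mk("EIKSVR", "swapped"))$state, "trimer")
  expect_equal(predict_oligomer("x", mk("KIKSVE", "p1_sub", "K"))$state,
               "trimer_tetramer_equilibrium")
  expect_equal(predict_oligomer("x", mk("AIKSVE", "p1_sub", "A"))$state, "tetramer")
  expect_equal(predict_oligomer("x", mk("QIKSVE", "p1_sub", "Q"))$state, "tetramer")
  expect_equal(predict_oligomer("x", mk("SIKSVE", "p1_sub", "S"))$state, "unknown")
  expect_equal(predict_oligomer("x", mk("RIKSVQ", "p6_sub", "Q"))$state, "unknown")
  expect_equal(predict_oligomer("x", mk("RPKSPE", "p2/p5_sub"))$state, "unknown")
  expect_equal(predict_oligomer("x", NULL)$state, "unknown")
  expect_equal(predict_oligomer("x", NULL, has_cc = FALSE)$state, "no_coiled_coil")
})

test_that("CA domain detection needs a C hit followed by a nearby acidic hit", {
  set.seed(8)
  c_rows <- tibble::tibble(id = paste0("c", 1:8),
                           seq = replicate(8, corofam:::mutate_seq("LKSILSQAIHDLVDGLRKHR", 0.05)))
  a_rows <- tibble::tibble(id = paste0("a", 1:8),
                           seq = replicate(8, corofam:::mutate_seq("DDEWEDDSDEEFEDA", 0.05)))
  c_prof <- build_pssm(c_rows); a_prof <- build_pssm(a_rows)

  ok <- tibble::tibble(id = "p1", protein = paste0(
    rand_prot(60), pssm_consensus(c_prof), rand_prot(10), pssm_consensus(a_prof)))
  hit <- find_ca_domain(ok, c_prof, a_prof, max_linker = 40)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$domain_name, "CA")
  expect_equal(hit$start, 61L)
  expect_equal(hit$end, nchar(ok$protein))

  # acidic stretch without an upstream C match
  no_c <- tibble::tibble(id = "p2", protein = paste0(rand_prot(60), pssm_consensus(a_prof)))
  expect_equal(nrow(find_ca_domain(no_c, c_prof, a_prof)), 0)

  # linker too long
  far <- tibble::tibble(id = "p3", protein = paste0(
    rand_prot(20), pssm_consensus(c_prof), rand_prot(60), pssm_consensus(a_prof)))
  expect_equal(nrow(find_ca_domain(far, c_prof, a_prof, max_linker = 40)), 0)
})

test_that("architecture assembly emits the canonical strings", {
  h <- function(seq_id, name, start, end, score = 50, source = "pssm") {
    tibble::tibble(seq_id = seq_id, domain_name = name, start = start,
                   end = end, score = score, source = source)
  }
  short <- dplyr::bind_rows(h("s", "CORO", 1, 390),
                            h("s", "CC", 420, 455, source = "annotation"))
  expect_equal(assemble_architecture(short)$architecture, "CORO-U-CC")

  tandem <- dplyr::bind_rows(h("t", "CORO", 1, 390), h("t", "CORO", 416, 805),
                             h("t", "CA", 816, 850))
  expect_equal(assemble_architecture(tandem)$architecture, "CORO-X-CORO-CA")

  cls4 <- dplyr::bind_rows(
    h("v", "CORO", 1, 390),
    h("v", "PH", c(411, 511, 611), c(510, 610, 710), source = "annotation"),
    h("v", "GEL", 711 + 80 * (0:4), 790 + 80 * (0:4), source = "annotation"),
    h("v", "VHP", 1111, 1145, source = "annotation"))
  a4 <- assemble_architecture(cls4)
  expect_equal(a4$architecture, "CORO-U-PHx3-GELx5-VHP")
  expect_equal(a4$n_ph, 3L)
  expect_true(a4$has_villin_domains)

  # overlap resolution: higher score wins, then annotation beats pssm
  ov <- dplyr::bind_rows(h("o", "CORO", 1, 390, score = 90),
                         h("o", "PH", 380, 420, score = 30, source = "annotation"))
  expect_equal(assemble_architecture(ov)$architecture, "CORO")
  tie <- dplyr::bind_rows(h("o2", "CORO", 1, 390, score = 50),
                          h("o2", "PH", 380, 420, score = 50, source = "annotation"))
  expect_equal(assemble_architecture(tie)$architecture, "PH")
})
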