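# Profile-based coronin-domain detection, trimerization-motif scanning with
# the oligomer-state rule table, CA-domain search, and domain-architecture
# assembly.

#' Build a position-specific scoring matrix from an alignment
#'
#' Per-column log-odds over the 20 amino acids:
#' `score = log2(((count + pseudocount * bg) / (n + pseudocount)) / bg)`,
#' with `n` the number of non-gap residues in the column. Gap cells are
#' excluded from the counts; `X` is ignored.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param columns Optional integer vector of alignment columns to use
#'   (default: all).
#' @param background Background frequency vector over [AA20] (sums to 1).
#' @param pseudocount Pseudocount mass distributed as `pseudocount * bg`.
#' @param cap Lower cap on scores (bits), standing in for minus infinity.
#' @return A `coro_pssm`: a 20 x width score matrix (rows named by residue)
#'   with the background and pseudocount attached as attributes.
#' @export
build_pssm <- function(aln, columns = NULL, background = rep(1 / 20, 20),
                       pseudocount = 1, cap = -10) {
  stopifnot(nrow(aln) >= 2, abs(sum(background) - 1) < 1e-9)
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  columns <- columns %||% seq_len(ncol(mat))
  stopifnot(all(columns >= 1), all(columns <= ncol(mat)))
  mat <- mat[, columns, drop = FALSE]
  bg <- setNames(background, AA20)
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) abort(sprintf("all-gap alignment column at position %d", columns[j]))
    counts <- table(factor(col, levels = AA20))
    freq <- (as.numeric(counts) + pseudocount * bg) / (length(col) + pseudocount)
    pmax(log2(freq / bg), cap)
  }, numeric(20))
  scores <- matrix(scores, nrow = 20, dimnames = list(AA20, NULL))
  structure(scores, class = c("coro_pssm", "matrix"),
            background = bg, pseudocount = pseudocount, cap = cap)
}

#' @export
print.coro_pssm <- function(x, ...) {
  cat(sprintf("<coro_pssm> width %d, pseudocount %g\n", ncol(x), attr(x, "pseudocount")))
  invisible(x)
}

#' Consensus sequence of a PSSM
#'
#' @param pssm A `coro_pssm`.
#' @return The string of column-wise best-scoring residues.
#' @export
pssm_consensus <- function(pssm) {
  paste(rownames(pssm)[apply(unclass(pssm), 2, which.max)], collapse = "")
}

pssm_window_scores <- function(protein, pssm) {
  chars <- strsplit(protein, "")[[1]]
  w <- ncol(pssm)
  n <- length(chars) - w + 1L
  if (n < 1) return(numeric(0))
  idx <- match(chars, rownames(pssm))  # NA for X: contributes 0
  total <- numeric(n)
  S <- unclass(pssm)
  for (k in seq_len(w)) {
    v <- S[cbind(idx[k:(k + n - 1L)], k)]
    v[is.na(v)] <- 0
    total <- total + v
  }
  total
}

greedy_nonoverlapping <- function(starts, ends, scores) {
  keep <- integer(0)
  ord <- order(scores, decreasing = TRUE)
  for (i in ord) {
    if (all(starts[i] > ends[keep] | ends[i] < starts[keep])) keep <- c(keep, i)
  }
  sort(keep)
}

#' Scan proteins for PSSM domain hits
#'
#' Slides the profile along each protein, keeps windows whose total score
#' reaches `threshold` bits per column, and resolves overlaps greedily by
#' score. A tandem (class-3-like) coronin yields two non-overlapping hits.
#'
#' @param records Record tibble (`id`, `protein`), or a single protein string.
#' @param pssm A `coro_pssm`.
#' @param domain_name Name to assign to hits (default `"CORO"`).
#' @param threshold Minimum mean score per column, in bits.
#' @return A tibble of hits (`seq_id`, `domain_name`, `start`, `end`,
#'   `score`, `source = "pssm"`); zero rows if nothing scores.
#' @export
scan_domain <- function(records, pssm, domain_name = "CORO", threshold = 0.5) {
  if (is.character(records)) records <- tibble(id = names(records) %||% "seq", protein = records)
  w <- ncol(pssm)
  out <- map(seq_len(nrow(records)), function(i) {
    sc <- pssm_window_scores(records$protein[i], pssm)
    cand <- which(sc >= threshold * w)
    if (length(cand) == 0) return(NULL)
    keep <- greedy_nonoverlapping(cand, cand + w - 1L, sc[cand])
    tibble(
      seq_id = records$id[i], domain_name = domain_name,
      start = as.integer(cand[keep]), end = as.integer(cand[keep] + w - 1L),
      score = sc[cand][keep], source = "pssm"
    )
  })
  bind_rows(out)
}

HYD_P2 <- c("I", "L", "V", "M")
HYD_P5 <- c("I", "L", "V")

#' Classify a 6-residue window against the trimerization motif
#'
#' The coiled-coil trimerization motif is R-[ILVM]-X-X-[ILV]-E: an
#' arginine--glutamate salt bridge shields the hydrophobic positions 2 and 5.
#' Variants are named by which invariant position is substituted.
#'
#' @param window A 6-character residue string.
#' @return A list with `variant` (one of `classical`, `swapped`, `p1_sub`,
#'   `p6_sub`, `p2/p5_sub`, `none`), `detail` (the substituting residue for
#'   `p1_sub`/`p6_sub`, else `NA`) and `rank` (preference order, 1 best).
#' @export
classify_motif <- function(window) {
  stopifnot(nchar(window) == 6)
  p <- strsplit(window, "")[[1]]
  hyd <- p[2] %in% HYD_P2 && p[5] %in% HYD_P5
  if (hyd && p[1] == "R" && p[6] == "E") {
    list(variant = "classical", detail = NA_character_, rank = 1L)
  } else if (hyd && p[1] == "E" && p[6] == "R") {
    list(variant = "swapped", detail = NA_character_, rank = 2L)
  } else if (hyd && p[6] == "E") {
    list(variant = "p1_sub", detail = p[1], rank = 3L)
  } else if (hyd && p[1] == "R") {
    list(variant = "p6_sub", detail = p[6], rank = 4L)
  } else if (p[1] == "R" && p[6] == "E") {
    list(variant = "p2/p5_sub", detail = NA_character_, rank = 5L)
  } else {
    list(variant = "none", detail = NA_character_, rank = NA_integer_)
  }
}

#' Find the trimerization motif in coiled-coil regions
#'
#' Scans every 6-mer of the coiled-coil region (or, absent annotation, the
#' C-terminal `tail_window` residues) and keeps the best window: a classical
#' match is preferred, then swapped, position-1 substitutions, position-6
#' substitutions, and position-2/5 substitutions; the leftmost window wins
#' ties.
#'
#' @param records Record tibble (`id`, `protein`).
#' @param cc_regions Optional tibble (`seq_id`, `start`, `end`) of
#'   coiled-coil annotations (1-based inclusive residues).
#' @param tail_window Length of the default C-terminal scan window.
#' @return A tibble (`seq_id`, `start`, `residues`, `variant`, `detail`) with
#'   one row per sequence in which any motif variant was found.
#' @export
find_trimerization_motif <- function(records, cc_regions = NULL, tail_window = 60L) {
  out <- map(seq_len(nrow(records)), function(i) {
    prot <- records$protein[i]
    n <- nchar(prot)
    reg <- c(max(1L, n - tail_window + 1L), n)
    if (!is.null(cc_regions)) {
      cc <- cc_regions[cc_regions$seq_id == records$id[i], ]
      if (nrow(cc) > 0) reg <- c(cc$start[1], min(cc$end[1], n))
    }
    if (reg[2] - reg[1] + 1 < 6) return(NULL)
    starts <- reg[1]:(reg[2] - 5L)
    # vectorized ranking over all windows; details resolved for the winner
    p1 <- substring(prot, starts, starts)
    p2 <- substring(prot, starts + 1L, starts + 1L)
    p5 <- substring(prot, starts + 4L, starts + 4L)
    p6 <- substring(prot, starts + 5L, starts + 5L)
    hyd <- p2 %in% HYD_P2 & p5 %in% HYD_P5
    ranks <- rep(NA_integer_, length(starts))
    ranks[p1 == "R" & p6 == "E" & !hyd] <- 5L
    ranks[hyd & p1 == "R" & p6 != "E"] <- 4L
    ranks[hyd & p1 != "R" & p6 == "E"] <- 3L
    ranks[hyd & p1 == "E" & p6 == "R"] <- 2L
    ranks[hyd & p1 == "R" & p6 == "E"] <- 1L
    if (all(is.na(ranks))) return(NULL)
    best <- which(ranks == min(ranks, na.rm = TRUE))[1]
    cls <- classify_motif(substr(prot, starts[best], starts[best] + 5L))
    tibble(
      seq_id = records$id[i], start = as.integer(starts[best]),
      residues = substr(prot, starts[best], starts[best] + 5L),
      variant = cls$variant, detail = cls$detail
    )
  })
  bind_rows(out)
}

oligomer_rule <- function(variant, detail) {
  if (is.na(variant) || variant == "none") {
    c("unknown", "no_motif")
  } else if (variant == "classical") {
    c("trimer", "classical_motif")
  } else if (variant == "swapped") {
    c("trimer", "salt_bridge_swapped")
  } else if (variant == "p1_sub") {
    switch(detail,
      K = c("trimer_tetramer_equilibrium", "p1_lysine"),
      A = c("tetramer", "p1_alanine"),
      Q = c("tetramer", "p1_glutamine"),
      c("unknown", "p1_other")
    )
  } else if (variant == "p6_sub") {
    if (identical(detail, "Q")) c("unknown", "p6_glutamine_unanalyzed") else c("unknown", "p6_other")
  } else {
    c("unknown", "p2p5_substituted")
  }
}

#' Predict oligomeric state from trimerization-motif evidence
#'
#' Encodes the experimental substitution record for the coiled-coil
#' trimerization motif: the classical motif and the salt-bridge-swapped form
#' predict trimers; arginine-to-lysine at position 1 gives a
#' concentration-dependent trimer/tetramer equilibrium; arginine to alanine
#' or glutamine gives tetramers; glutamine for the position-6 glutamate is
#' unanalyzed (unknown); other substitutions and motif absence are unknown;
#' sequences without a coiled-coil (e.g. tandem class-3 coronins) get
#' `no_coiled_coil`.
#'
#' @param ids Character vector of sequence ids to call.
#' @param motifs Motif-hit tibble from [find_trimerization_motif()].
#' @param has_cc Logical scalar or named vector per id: does the sequence
#'   have a coiled-coil region?
#' @return A tibble (`seq_id`, `state`, `rule_id`, `variant`, `residues`).
#' @export
predict_oligomer <- function(ids, motifs = NULL, has_cc = TRUE) {
  cc <- if (length(has_cc) == 1 && is.null(names(has_cc))) {
    setNames(rep(has_cc, length(ids)), ids)
  } else has_cc
  out <- map(ids, function(id) {
    if (!isTRUE(cc[[id]])) {
      return(tibble(seq_id = id, state = "no_coiled_coil", rule_id = "no_cc",
                    variant = NA_character_, residues = NA_character_))
    }
    m <- if (is.null(motifs) || nrow(motifs) == 0) NULL else motifs[motifs$seq_id == id, ]
    if (is.null(m) || nrow(m) == 0) {
      r <- oligomer_rule("none", NA_character_)
      return(tibble(seq_id = id, state = r[1], rule_id = r[2],
                    variant = "none", residues = NA_character_))
    }
    r <- oligomer_rule(m$variant[1], m$detail[1])
    tibble(seq_id = id, state = r[1], rule_id = r[2],
           variant = m$variant[1], residues = m$residues[1])
  })
  bind_rows(out)
}

#' Find a CA (central + acidic) domain
#'
#' Looks for a central-region profile hit followed, within a linker of
#' variable but bounded length, by an acidic-region profile hit; the two are
#' merged into one CA domain hit, as in the C-termini of tandem coronins.
#'
#' @param records Record tibble (`id`, `protein`).
#' @param c_profile,a_profile `coro_pssm` profiles for the C and A regions.
#' @param max_linker Maximum residues between the C and A hits.
#' @param threshold Minimum mean score per column (bits) for each sub-hit.
#' @return A tibble of combined hits (`seq_id`, `domain_name = "CA"`,
#'   `start`, `end`, `score`, `source = "pssm"`); zero rows when no pair
#'   qualifies.
#' @export
find_ca_domain <- function(records, c_profile, a_profile, max_linker = 40L,
                           threshold = 0.5) {
  c_hits <- scan_domain(records, c_profile, "C", threshold)
  a_hits <- scan_domain(records, a_profile, "A", threshold)
  empty <- tibble(seq_id = character(0), domain_name = character(0),
                  start = integer(0), end = integer(0), score = numeric(0),
                  source = character(0))
  if (nrow(c_hits) == 0 || nrow(a_hits) == 0) return(empty)
  out <- map(records$id, function(id) {
    ch <- c_hits[c_hits$seq_id == id, ]
    ah <- a_hits[a_hits$seq_id == id, ]
    if (nrow(ch) == 0 || nrow(ah) == 0) return(NULL)
    pairs <- tidyr::expand_grid(ci = seq_len(nrow(ch)), ai = seq_len(nrow(ah)))
    gap <- ah$start[pairs$ai] - ch$end[pairs$ci] - 1L
    ok <- gap >= 0 & gap <= max_linker
    if (!any(ok)) return(NULL)
    sc <- ch$score[pairs$ci] + ah$score[pairs$ai]
    best <- which(ok)[which.max(sc[ok])]
    tibble(
      seq_id = id, domain_name = "CA",
      start = ch$start[pairs$ci[best]], end = ah$end[pairs$ai[best]],
      score = sc[best], source = "pssm"
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) empty else res
}

SOURCE_PRIORITY <- c(annotation = 3, pssm = 2, pattern = 1)

#' Assemble domain architectures from hits
#'
#' Resolves overlapping hits (higher score wins, then annotation over pssm
#' over pattern) and emits a canonical architecture string: domains in
#' sequence order, runs of the same domain collapsed as `NAMExN`, and
#' unannotated stretches of at least `min_gap` residues rendered `U` (unique
#' region) — or `X` between two coronin domains, the tandem linker.
#'
#' @param hits Domain-hit tibble (`seq_id`, `domain_name`, `start`, `end`,
#'   `score`, `source`), combining PSSM hits and external annotations.
#' @param min_gap Minimum inter-domain gap (residues) rendered as a unique
#'   region token.
#' @return A tibble (`seq_id`, `architecture`, `n_coro`, `n_ph`, `has_cc`,
#'   `has_villin_domains`, `hits` list-column of the retained hits).
#' @export
assemble_architecture <- function(hits, min_gap = 15L) {
  out <- map(unique(hits$seq_id), function(id) {
    h <- hits[hits$seq_id == id, ]
    pri <- SOURCE_PRIORITY[h$source]
    pri[is.na(pri)] <- 0
    ord <- order(-h$score, -pri)
    keep <- integer(0)
    for (i in ord) {
      if (all(h$start[i] > h$end[keep] | h$end[i] < h$start[keep])) keep <- c(keep, i)
    }
    h <- h[sort(keep), ]
    h <- h[order(h$start), ]
    tokens <- character(0)
    for (i in seq_len(nrow(h))) {
      if (i > 1) {
        gap <- h$start[i] - h$end[i - 1] - 1L
        if (gap >= min_gap) {
          tandem <- h$domain_name[i] == "CORO" && h$domain_name[i - 1] == "CORO"
          tokens <- c(tokens, if (tandem) "X" else "U")
        }
      }
      tokens <- c(tokens, h$domain_name[i])
    }
    r <- rle(tokens)
    arch <- paste(ifelse(r$lengths > 1 & !r$values %in% c("U", "X"),
                         paste0(r$values, "x", r$lengths), r$values),
                  collapse = "-")
    tibble(
      seq_id = id, architecture = arch,
      n_coro = sum(h$domain_name == "CORO"),
      n_ph = sum(h$domain_name == "PH"),
      has_cc = any(h$domain_name == "CC"),
      has_villin_domains = any(h$domain_name %in% c("PH", "GEL", "VHP")),
      hits = list(h)
    )
  })
  bind_rows(out)
}
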