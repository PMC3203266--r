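# Distance/NJ utilities, class assignment from monophyletic grouping with
# reference leaves, the combined architecture+tree classification rule, and
# conservation-logo information content.

#' Pairwise identity distance matrix from an alignment
#'
#' Distance is `1 - fractional identity` computed over columns where both
#' rows are non-gap. Pairs sharing fewer than `min_shared` columns get `NA`
#' (undefined) rather than an imputed value.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param region Optional integer vector of columns to restrict to.
#' @param min_shared Minimum mutually non-gap columns for a defined distance.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids, and
#'   attribute `n_shared` (matrix of shared-column counts).
#' @export
identity_matrix <- function(aln, region = NULL, min_shared = 10L) {
  stopifnot(nrow(aln) >= 2)
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  region <- region %||% seq_len(ncol(mat))
  stopifnot(length(region) > 0)
  mat <- mat[, region, drop = FALSE]
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  shared <- matrix(0L, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      shared[i, j] <- shared[j, i] <- sum(ok)
      if (sum(ok) < min_shared) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- 1 - mean(mat[i, ok] == mat[j, ok])
      }
    }
  }
  attr(d, "n_shared") <- shared
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining. On additive matrices the induced
#' path metric reproduces the input exactly, so the true topology is
#' recovered. Intended for small synthetic analyses; large published trees
#' remain external inputs.
#'
#' @param dm Symmetric distance matrix with ids as dimnames; no `NA`s.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (anyNA(dm)) {
    abort("distance matrix has undefined entries; remove the affected taxa and retry")
  }
  n <- nrow(dm)
  if (n < 3) abort("need at least 3 taxa")
  labels <- colnames(dm) %||% paste0("t", seq_len(n))
  node <- labels  # newick substring per active cluster
  D <- dm
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    k <- arrayInd(which.min(Q), dim(Q))
    i <- min(k); j <- max(k)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", node[i], li, node[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, u = du), u = c(du, 0))[-c(i, j), -c(i, j), drop = FALSE]
    node <- c(node[-c(i, j)], new_node)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", node[1], la, node[2], lb, node[3], lc)
  ape::read.tree(text = nwk)
}

ref_table <- function(references) {
  if (is.data.frame(references)) {
    tibble(id = references$id, class = references$class)
  } else {
    tibble(id = names(references), class = unname(references))
  }
}

#' Assign a class from the smallest reference-containing clade
#'
#' The tree is rooted at the user-supplied outgroup, or at the midpoint when
#' none is given (published coronin trees are unrooted). The query receives
#' class `C` exactly when the smallest clade containing the query and at
#' least one reference leaf holds references of class `C` only; a mixed
#' smallest clade (e.g. a non-metazoan short coronin equally related to
#' class-1 and class-2) leaves it unclassified.
#'
#' @param tree A `phylo` tree containing the query and reference leaves.
#' @param references Named character vector (id to class) or tibble
#'   (`id`, `class`).
#' @param query_id Leaf to classify.
#' @param outgroup Optional outgroup leaf name used for rooting.
#' @return A one-row tibble (`seq_id`, `class`, `basis = "tree"`,
#'   `supporting_clade` list-column of leaf names).
#' @export
assign_class <- function(tree, references, query_id, outgroup = NULL) {
  refs <- ref_table(references)
  refs <- refs[refs$id != query_id, ]
  if (!query_id %in% tree$tip.label) abort(sprintf("query '%s' absent from tree", query_id))
  if (!any(refs$id %in% tree$tip.label)) abort("no reference leaves present in tree")
  rooted <- if (!is.null(outgroup) && outgroup %in% tree$tip.label) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
  tip <- which(rooted$tip.label == query_id)
  node <- rooted$edge[rooted$edge[, 2] == tip, 1]
  repeat {
    tips <- rooted$tip.label[phangorn::Descendants(rooted, node, type = "tips")[[1]]]
    in_clade <- refs[refs$id %in% tips, ]
    if (nrow(in_clade) > 0) break
    up <- rooted$edge[rooted$edge[, 2] == node, 1]
    if (length(up) == 0) break  # reached the root
    node <- up
  }
  classes <- unique(in_clade$class)
  cls <- if (length(classes) == 1) classes else "unclassified"
  tibble(seq_id = query_id, class = cls, basis = "tree", supporting_clade = list(tips))
}

#' Classify coronins from architecture plus tree grouping
#'
#' Applies the combined rule: two coronin-domain hits make a tandem class-3;
#' a coronin domain together with villin-derived domains (PH, gelsolin, VHP)
#' makes a class-4; a single coronin domain is classified by its grouping
#' with reference leaves in the domain tree (class-1 and class-2 calls always
#' rest on tree evidence), and stays unclassified without tree support.
#'
#' @param records Record tibble (`id`, ...).
#' @param architectures Output of [assemble_architecture()].
#' @param tree Optional `phylo` domain tree.
#' @param references Optional reference labels for [assign_class()].
#' @param outgroup Optional outgroup for rooting.
#' @return A tibble (`seq_id`, `class`, `basis`, `supporting_clade`).
#' @export
classify_pipeline <- function(records, architectures, tree = NULL,
                              references = NULL, outgroup = NULL) {
  out <- map(records$id, function(id) {
    a <- architectures[architectures$seq_id == id, ]
    if (nrow(a) == 0 || a$n_coro[1] == 0) {
      return(tibble(seq_id = id, class = "unclassified", basis = "none",
                    supporting_clade = list(character(0))))
    }
    if (a$n_coro[1] >= 2) {
      return(tibble(seq_id = id, class = "class-3", basis = "architecture",
                    supporting_clade = list(character(0))))
    }
    if (a$has_villin_domains[1]) {
      return(tibble(seq_id = id, class = "class-4", basis = "architecture",
                    supporting_clade = list(character(0))))
    }
    if (!is.null(tree) && !is.null(references) && id %in% tree$tip.label) {
      return(assign_class(tree, references, id, outgroup = outgroup))
    }
    tibble(seq_id = id, class = "unclassified", basis = "none",
           supporting_clade = list(character(0)))
  })
  bind_rows(out)
}

#' Per-column information content and letter heights (sequence logo)
#'
#' Shannon information content per alignment column:
#' `IC = log2(20) - H` with `H` the entropy of the non-gap residue
#' frequencies; each residue's letter height is `freq * IC`. Columns that are
#' entirely gaps get `NA`. The small-sample correction
#' `(20 - 1) / (2 ln(2) n)` can be subtracted optionally.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param region Optional columns to restrict to.
#' @param small_sample_correction Apply the correction (default off).
#' @return A `coro_logo` tibble in long form (`column`, `residue`, `freq`,
#'   `height`, `ic`), one row per residue observed in each column.
#' @export
sequence_logo <- function(aln, region = NULL, small_sample_correction = FALSE) {
  stopifnot(nrow(aln) >= 2)
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  region <- region %||% seq_len(ncol(mat))
  out <- map(region, function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) {
      return(tibble(column = j, residue = NA_character_, freq = NA_real_,
                    height = NA_real_, ic = NA_real_))
    }
    f <- table(col) / length(col)
    h <- -sum(f * log2(f))
    ic <- log2(20) - h
    if (small_sample_correction) ic <- max(0, ic - (20 - 1) / (2 * log(2) * length(col)))
    tibble(column = j, residue = names(f), freq = as.numeric(f),
           height = as.numeric(f) * ic, ic = ic)
  })
  out <- bind_rows(out)
  class(out) <- c("coro_logo", class(out))
  out
}
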