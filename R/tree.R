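#' Pairwise distance matrix from a protein alignment
#'
#' The p-distance of a pair is the fraction of mismatching residues over
#' the columns where both rows are ungapped; the Poisson correction maps
#' it to `-ln(1 - p)` expected substitutions per site.
#'
#' @param msa A [msa()] with at least two rows.
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by the
#'   alignment row ids.
#' @export
distance_matrix <- function(msa, correction = c("none", "poisson")) {
  stopifnot(inherits(msa, "protein_msa"))
  correction <- match.arg(correction)
  n <- length(msa$ids)
  if (n < 2L) stop("need at least 2 aligned rows")
  chars <- do.call(rbind, strsplit(msa$seqs, ""))
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(shared))
        stop("overlap error: rows '", msa$ids[i], "' and '", msa$ids[j],
             "' share no ungapped columns")
      p <- mean(chars[i, shared] != chars[j, shared])
      if (correction == "poisson") {
        if (p >= 1)
          stop("saturation error: p-distance of 1 between '", msa$ids[i],
               "' and '", msa$ids[j], "' cannot be Poisson-corrected")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || is.null(rownames(d)))
    stop("matrix error: need a square labelled matrix")
  if (!all(is.finite(d)) || any(d < 0))
    stop("matrix error: entries must be finite and non-negative")
  if (any(abs(d - t(d)) > 1e-12)) stop("matrix error: matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("matrix error: diagonal must be zero")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}), returned as an unrooted
#' `phylo` object with a trifurcating root.  Negative branch lengths --
#' an artifact NJ can produce on non-additive inputs -- are clamped to
#' zero with the deficit transferred to the sibling edge, so leaf-to-leaf
#' path lengths are preserved.  For exactly two taxa a single split edge
#' is returned.
#'
#' @param d Distance matrix as from [distance_matrix()].
#' @return An \pkg{ape} `phylo` tree whose tip labels are the matrix
#'   labels.
#' @export
nj_tree <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                         edge.length = rep(d[1, 2] / 2, 2),
                         tip.label = rownames(d), Nnode = 1L),
                    class = "phylo")
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib)) {
      # transfer the deficit so path lengths through the parent persist
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write a tree in Newick format
#'
#' @param tree An \pkg{ape} `phylo` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Parse a Newick string or file
#'
#' @param text A Newick string (terminated by `;`).
#' @return An \pkg{ape} `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(gsub("[^(]", "", text)) != nchar(gsub("[^)]", "", text)))
    stop("parse error: unbalanced parentheses at offset ",
         max(regexpr("\\(", text), regexpr("\\)", text)))
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("parse error: invalid Newick text")
  tr
}
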