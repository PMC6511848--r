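# Gene-pair representations: the sum of the two members' embedding rows.
# The inner product of two pair vectors expands into the four cross-member
# similarities, so it is large only when members of one pair are each
# similar to members of the other -- in high dimension unrelated embedding
# vectors are nearly orthogonal and the cross terms vanish.

#' Representation of a gene pair
#'
#' @param C embedding coordinate matrix (rows named by gene id), e.g. from
#'   [coef.munk()].
#' @param i,j gene identifiers; order is irrelevant.
#' @return numeric vector `C[i, ] + C[j, ]` with attribute `genes` holding
#'   the sorted pair.
#' @export
pair_representation <- function(C, i, j) {
  missing <- setdiff(c(i, j), rownames(C))
  if (length(missing) > 0L) {
    stop_input("gene id(s) not in embedding: ", paste(missing, collapse = ", "))
  }
  v <- C[i, ] + C[j, ]
  attr(v, "genes") <- sort(c(i, j))
  v
}

#' Similarity of two gene pairs
#'
#' The inner product of two pair representations; algebraically equal to
#' the sum of the four member-to-member similarities.
#'
#' @param p,q pair vectors from [pair_representation()] (any equal-length
#'   numeric vectors are accepted).
#' @return scalar inner product.
#' @export
pair_score <- function(p, q) {
  if (length(p) != length(q)) stop_input("pair vectors have different dimensions")
  sum(as.numeric(p) * as.numeric(q))
}
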