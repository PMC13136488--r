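#' @useDynLib rnacircgen, .registration = TRUE
#' @importFrom stats median quantile rnorm runif sd setNames density cor cutree
#'   dist hclust
#' @importFrom utils read.csv write.csv head modifyList
"_PACKAGE"

# Canonical interaction order for a 3-node circuit.  Every module indexes the
# six unique pairwise interactions exclusively through this packing.
PAIR_NAMES <- c("k11", "k12", "k13", "k22", "k23", "k33")

#' Nucleotide frequencies used for random RNA sequences
#'
#' Genome-wide nucleotide proportions of *Escherichia coli* transcripts, the
#' default composition from which circuit RNAs are drawn.
#' @export
ECOLI_NT_FREQS <- c(A = 0.2451, C = 0.2458, G = 0.2622, U = 0.2469)

#' Sampling configuration for circuit generation
#'
#' Bundles everything needed to draw either random RNA sequences or random
#' binding-energy vectors: number of circuits, nodes per circuit, sequence
#' length, nucleotide frequencies, the energy range sampled uniformly, and the
#' RNG seed recorded in all outputs.
#'
#' @param n_circuits positive integer, number of circuits to draw.
#' @param n_nodes number of RNA species per circuit (default 3).
#' @param seq_length RNA length in nucleotides (default 20).
#' @param nucleotide_freqs named numeric of 4 probabilities (A, C, G, U)
#'   summing to 1; defaults to [ECOLI_NT_FREQS].
#' @param energy_range numeric `c(low, high)` in kcal/mol with
#'   `low < high <= 0`; default `c(-30, 0)`.
#' @param seed integer RNG seed.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(n_circuits, n_nodes = 3L, seq_length = 20L,
                            nucleotide_freqs = ECOLI_NT_FREQS,
                            energy_range = c(-30, 0), seed = 1L) {
  if (!is.numeric(n_circuits) || length(n_circuits) != 1L || n_circuits < 1)
    stop("`n_circuits` must be a positive integer", call. = FALSE)
  if (length(nucleotide_freqs) != 4L || any(nucleotide_freqs < 0) ||
      abs(sum(nucleotide_freqs) - 1) > 1e-9)
    stop("`nucleotide_freqs` must be 4 nonnegative probabilities summing to 1",
         call. = FALSE)
  if (length(energy_range) != 2L || energy_range[1] >= energy_range[2] ||
      energy_range[2] > 0)
    stop("`energy_range` must satisfy low < high <= 0 (kcal/mol)",
         call. = FALSE)
  structure(list(
    n_circuits = as.integer(n_circuits),
    n_nodes = as.integer(n_nodes),
    seq_length = as.integer(seq_length),
    nucleotide_freqs = setNames(as.numeric(nucleotide_freqs),
                                c("A", "C", "G", "U")),
    energy_range = as.numeric(energy_range),
    seed = as.integer(seed)
  ), class = "sampling_config")
}

n_pairs <- function(n_nodes) n_nodes * (n_nodes + 1L) %/% 2L

#' Draw random RNA sequence circuits
#'
#' Each circuit consists of `n_nodes` RNA sequences whose bases are drawn
#' i.i.d. per position from the configured nucleotide frequencies.  Sequences
#' use the uppercase RNA alphabet (A, C, G, U).
#'
#' @param config a [sampling_config()].
#' @return A list of circuits; each element has `circuit_id` and `sequences`
#'   (character vector of length `n_nodes`).
#' @export
sample_sequences <- function(config) {
  stopifnot(inherits(config, "sampling_config"))
  set.seed(config$seed)
  bases <- names(config$nucleotide_freqs)
  lapply(seq_len(config$n_circuits), function(i) {
    seqs <- vapply(seq_len(config$n_nodes), function(j) {
      paste(sample(bases, config$seq_length, replace = TRUE,
                   prob = config$nucleotide_freqs), collapse = "")
    }, character(1))
    list(circuit_id = sprintf("seq_%06d", i), sequences = seqs,
         seed = config$seed)
  })
}

validate_rna <- function(seqs, seq_length = NULL) {
  if (any(grepl("[^ACGU]", seqs)))
    stop("sequences must use the uppercase RNA alphabet {A,C,G,U}; ",
         "found other characters (T is rejected, not converted)",
         call. = FALSE)
  if (!is.null(seq_length) && any(nchar(seqs) != seq_length))
    stop("all sequences must have length ", seq_length, call. = FALSE)
  invisible(TRUE)
}

#' Draw circuits directly as binding-energy vectors
#'
#' Bypasses sequences entirely: each of the six unique pairwise interactions
#' is drawn independently and uniformly on `energy_range` (by sampling on
#' [0, 1] and scaling), giving parameter-sampled circuits in kcal/mol.
#'
#' @param config a [sampling_config()].
#' @return A data.frame with columns `circuit_id`, `k11`, `k12`, `k13`,
#'   `k22`, `k23`, `k33` and attribute `seed`.
#' @export
sample_energy_circuits <- function(config) {
  stopifnot(inherits(config, "sampling_config"))
  set.seed(config$seed)
  m <- n_pairs(config$n_nodes)
  lo <- config$energy_range[1]; hi <- config$energy_range[2]
  u <- matrix(runif(config$n_circuits * m), ncol = m)
  e <- lo + u * (hi - lo)
  colnames(e) <- if (config$n_nodes == 3L) PAIR_NAMES else
    pair_names(config$n_nodes)
  out <- data.frame(circuit_id = sprintf("par_%06d", seq_len(config$n_circuits)),
                    e, stringsAsFactors = FALSE)
  attr(out, "seed") <- config$seed
  out
}

pair_names <- function(n_nodes) {
  idx <- pair_index(n_nodes)
  sprintf("k%d%d", idx[, 1], idx[, 2])
}

pair_index <- function(n_nodes = 3L) {
  do.call(rbind, lapply(seq_len(n_nodes), function(i)
    cbind(i, i:n_nodes)))
}

#' Pack a symmetric interaction matrix into its canonical vector
#'
#' The upper triangle (including the diagonal) is listed row-major, which for
#' 3 nodes gives the canonical order `[k11, k12, k13, k22, k23, k33]`.
#'
#' @param mat symmetric numeric matrix of pairwise interactions.
#' @param tol asymmetry tolerance.
#' @return Numeric vector of length `n(n+1)/2`.
#' @export
pack_energies <- function(mat, tol = 1e-12) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > tol)
    stop("interaction matrix must be symmetric", call. = FALSE)
  idx <- pair_index(nrow(mat))
  setNames(mat[idx], pair_names(nrow(mat)))
}

#' Unpack a canonical interaction vector into a symmetric matrix
#'
#' Inverse of [pack_energies()].
#'
#' @param v numeric vector of length `n(n+1)/2`.
#' @return Symmetric `n x n` matrix.
#' @export
unpack_energies <- function(v) {
  n <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("vector length is not n(n+1)/2 for any integer n", call. = FALSE)
  n <- as.integer(round(n))
  mat <- matrix(0, n, n)
  idx <- pair_index(n)
  mat[idx] <- v
  mat[idx[, c(2, 1)]] <- v
  mat
}

energy_matrix <- function(circuits) {
  as.matrix(circuits[, PAIR_NAMES, drop = FALSE])
}

#' Write circuit sequences to FASTA
#'
#' One record per node, id `"{circuit_id}_node{k}"`.
#'
#' @param circuits list from [sample_sequences()].
#' @param path output FASTA file.
#' @export
write_circuit_fasta <- function(circuits, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O", call. = FALSE)
  seqs <- unlist(lapply(circuits, `[[`, "sequences"))
  ids <- unlist(lapply(circuits, function(cc)
    sprintf("%s_node%d", cc$circuit_id, seq_along(cc$sequences))))
  x <- Biostrings::RNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read circuit sequences from FASTA
#'
#' Records must be named `"{circuit_id}_node{k}"`; consecutive nodes are
#' regrouped into circuits.
#'
#' @param path FASTA file written by [write_circuit_fasta()].
#' @return List of circuits as produced by [sample_sequences()].
#' @export
read_circuit_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O", call. = FALSE)
  x <- Biostrings::readRNAStringSet(path)
  ids <- sub("_node[0-9]+$", "", names(x))
  lapply(split(as.character(x), factor(ids, levels = unique(ids))),
         function(s) list(circuit_id = unique(sub("_node.*", "", names(s))),
                          sequences = unname(s)))
}
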