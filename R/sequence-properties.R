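# Sequence-derived physicochemical properties. All scales are vendored
# published constants (see protparam-tables.R): Kyte & Doolittle (1982)
# hydropathy, Guruprasad et al. (1990) dipeptide instability weights,
# average residue masses, and an EMBOSS-style pKa set for the isoelectric
# point. Properties are recomputed from sequence so no annotation database
# is needed.

# pKa set (EMBOSS convention) for the Henderson-Hasselbalch net-charge model
.pka <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

.std_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.ambiguous_aa <- c("B", "Z", "X", "U", "O")

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(chars %in% c(.std_aa, .ambiguous_aa)))
  if (length(bad) > 0)
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  chars
}

# net charge at a given pH under the Henderson-Hasselbalch model
.net_charge <- function(chars, pH) {
  pos <- c(.pka$nterm, .pka$positive[chars[chars %in% names(.pka$positive)]])
  neg <- c(.pka$cterm, .pka$negative[chars[chars %in% names(.pka$negative)]])
  sum(1 / (1 + 10^(pH - pos))) - sum(1 / (1 + 10^(neg - pH)))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in \[0, 14\] where the Henderson-Hasselbalch net charge of
#' the sequence vanishes, by bisection to `|charge| < tol`.
#'
#' @param sequence Amino-acid string.
#' @param tol Charge tolerance (default 1e-4).
#' @return The isoelectric point (pH).
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  chars <- .check_sequence(sequence)
  chars <- chars[chars %in% .std_aa]
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .net_charge(chars, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties of a protein sequence
#'
#' The six features of the workflow-bias analysis, computed from sequence:
#' molecular weight (sum of average residue masses plus one water), sequence
#' length, isoelectric point (bisection on the net-charge model), GRAVY
#' (mean Kyte-Doolittle hydropathy), aromaticity (F+W+Y fraction of length)
#' and the Guruprasad instability index
#' (`10/length * sum of dipeptide DIWV weights`).
#'
#' Ambiguous or non-standard residues (B, Z, X, U, O) count toward the
#' length but are excluded from the scale averages, the mass sum and the
#' dipeptide walk (a dipeptide containing one contributes no weight).
#'
#' @param sequence Amino-acid string (20-letter alphabet plus B/Z/X/U/O).
#' @param protein_id Optional id carried into the output.
#' @return One-row data frame: `protein_id`, `molecular_weight`, `length`,
#'   `isoelectric_point`, `gravy`, `aromaticity`, `instability_index`.
#' @export
sequence_properties <- function(sequence, protein_id = NA_character_) {
  chars <- .check_sequence(sequence)
  len <- length(chars)
  std <- chars[chars %in% .std_aa]
  if (length(std) == 0) stop("sequence contains no standard residues")
  mw <- sum(.residue_mass[std]) + .water_mass
  gravy <- mean(.kyte_doolittle[std])
  arom <- sum(std %in% c("F", "W", "Y")) / len
  # dipeptide walk over consecutive standard-residue pairs
  ii <- 0
  if (len >= 2) {
    a <- chars[-len]; b <- chars[-1]
    ok <- a %in% .std_aa & b %in% .std_aa
    if (any(ok)) ii <- sum(.diwv[cbind(a[ok], b[ok])])
  }
  instability <- 10 / len * ii
  data.frame(protein_id = protein_id, molecular_weight = mw, length = len,
             isoelectric_point = isoelectric_point(sequence),
             gravy = gravy, aromaticity = arom,
             instability_index = instability,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname sequence_properties
#' @param sequences Named character vector (e.g. from
#'   [read_fasta_sequences()]).
#' @return `sequence_properties_table()` returns one row per sequence.
#' @export
sequence_properties_table <- function(sequences) {
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  do.call(rbind, lapply(names(sequences), function(id)
    sequence_properties(sequences[[id]], protein_id = id)))
}
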