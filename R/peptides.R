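# Sequence arithmetic: peptide masses, random-coil hydrodynamics, oligomer
# inference and sliding-window fragment generation.

# Average (not monoisotopic) residue masses in Da, standard 20 canonical
# amino acids (residue = amino acid minus water).
AA_AVERAGE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MASS <- 18.01528

.CAP_LEVELS <- list(
  n_term = c("free", "acetyl", "methyl"),
  c_term = c("free", "amide", "methyl")
)

#' Construct a peptide sequence with parent-protein numbering and terminal caps
#'
#' @param residues Character scalar of one-letter amino-acid codes (20
#'   canonical codes only).
#' @param start_number Integer, parent-protein number of the first residue
#'   (1-based); residue \code{i} carries number \code{start_number + i - 1}.
#' @param n_term_cap One of \code{"free"}, \code{"acetyl"}, \code{"methyl"}.
#' @param c_term_cap One of \code{"free"}, \code{"amide"}, \code{"methyl"}.
#' @return An object of class \code{"peptide_sequence"}.
#' @examples
#' nls1 <- peptide_sequence("AKKKSTGSSTWPLDPGVEVTLTMKVAS", start_number = 58)
#' average_mass(nls1)
#' @export
peptide_sequence <- function(residues, start_number = 1L,
                             n_term_cap = "free", c_term_cap = "free") {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("'residues' must be a non-empty character scalar")
  residues <- toupper(residues)
  codes <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!codes %in% names(AA_AVERAGE_MASS))
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d", codes[bad[1L]],
                 bad[1L]))
  start_number <- as.integer(start_number)
  if (is.na(start_number) || start_number < 1L)
    stop("'start_number' must be an integer >= 1")
  n_term_cap <- match.arg(n_term_cap, .CAP_LEVELS$n_term)
  c_term_cap <- match.arg(c_term_cap, .CAP_LEVELS$c_term)
  structure(
    list(residues = residues, start_number = start_number,
         n_term_cap = n_term_cap, c_term_cap = c_term_cap),
    class = "peptide_sequence"
  )
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("peptide %s (residues %d-%d, N-term %s, C-term %s)\n",
              x$residues, x$start_number,
              x$start_number + nchar(x$residues) - 1L,
              x$n_term_cap, x$c_term_cap))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) nchar(x$residues)

#' Terminal cap mass adjustments
#'
#' Mass deltas (Da) applied on top of the free-peptide average mass.
#' Acetylation of the N-terminus replaces an amide hydrogen with an acetyl
#' group (+42.037); C-terminal amidation replaces the hydroxyl with an amine
#' (-0.985); a methyl cap adds a CH2 relative to the free terminus (+14.027).
#' The deltas are exposed so an alternative cap chemistry can be supplied.
#'
#' @param acetyl,amide,methyl Numeric mass deltas in Da.
#' @return Named list of cap deltas.
#' @export
cap_mass_deltas <- function(acetyl = 42.0367, amide = -0.9847,
                            methyl = 14.0266) {
  list(acetyl = acetyl, amide = amide, methyl = methyl, free = 0)
}

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water, adjusted for terminal caps.
#'
#' @param seq A \code{\link{peptide_sequence}} (or a plain character string,
#'   taken as a free peptide).
#' @param deltas Cap mass adjustments, see \code{\link{cap_mass_deltas}}.
#' @return Mass in Da.
#' @examples
#' average_mass(peptide_sequence("G"))  # 75.07
#' @export
average_mass <- function(seq, deltas = cap_mass_deltas()) {
  if (is.character(seq)) seq <- peptide_sequence(seq)
  stopifnot(inherits(seq, "peptide_sequence"))
  codes <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  mass <- sum(AA_AVERAGE_MASS[codes]) + .WATER_MASS
  cap_delta <- function(cap) {
    if (identical(cap, "free")) 0 else deltas[[cap]]
  }
  mass + cap_delta(seq$n_term_cap) + cap_delta(seq$c_term_cap)
}

#' Sliding-window fragments of a peptide
#'
#' Divides a peptide into overlapping fragments of \code{window} residues
#' shifted by \code{step}. All fragments receive methyl caps at both termini,
#' except the last fragment whose C-terminus keeps the parent's cap (for an
#' amidated parent the terminal \code{-NH2} moiety is maintained). This
#' capping avoids spurious charged termini that do not exist in the parent
#' main chain. Residue numbering is inherited from the parent.
#'
#' @param seq A \code{\link{peptide_sequence}}.
#' @param window Fragment length in residues (default 7).
#' @param step Shift between consecutive fragments (default 2).
#' @return A data.frame of class \code{"fragment_set"} with columns
#'   \code{fragment_id}, \code{start_number}, \code{end_number},
#'   \code{sequence}, \code{nterm_cap}, \code{cterm_cap}; the parent is
#'   attached as attribute \code{"parent"}.
#' @examples
#' nls1 <- peptide_sequence("AKKKSTGSSTWPLDPGVEVTLTMKVAS", start_number = 58,
#'                          n_term_cap = "acetyl", c_term_cap = "amide")
#' make_fragments(nls1)  # 11 fragments, A58..G64 through L78..S84
#' @export
make_fragments <- function(seq, window = 7L, step = 2L) {
  stopifnot(inherits(seq, "peptide_sequence"))
  window <- as.integer(window); step <- as.integer(step)
  L <- nchar(seq$residues)
  if (window < 1L || step < 1L) stop("'window' and 'step' must be >= 1")
  if (window > L)
    stop(sprintf("window (%d) exceeds peptide length (%d)", window, L))
  n_frag <- (L - window) %/% step + 1L
  if ((L - window) %% step != 0L)
    warning(sprintf(
      "(length - window) not divisible by step; last %d residue(s) only covered by earlier windows",
      (L - window) %% step))
  offs <- (seq_len(n_frag) - 1L) * step
  frag_seq <- substring(seq$residues, offs + 1L, offs + window)
  start_num <- seq$start_number + offs
  cterm <- rep("methyl", n_frag)
  # the final fragment keeps the parent's C-terminal moiety
  cterm[n_frag] <- seq$c_term_cap
  out <- data.frame(
    fragment_id = seq_len(n_frag),
    start_number = start_num,
    end_number = start_num + window - 1L,
    sequence = frag_seq,
    nterm_cap = rep("methyl", n_frag),
    cterm_cap = cterm,
    stringsAsFactors = FALSE
  )
  attr(out, "parent") <- seq
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Random-coil hydrodynamic scaling parameters
#'
#' Empirical scaling \eqn{R_h = c \cdot MW^{e}} with \eqn{R_h} in nm and MW in
#' Da; the default coefficient 0.027 nm Da^-1/2 and exponent 1/2 describe a
#' random-coil (denatured-like) polypeptide.
#'
#' @param coefficient Scaling coefficient in nm Da^(-exponent); must be > 0.
#' @param exponent Dimensionless scaling exponent.
#' @return Named list of class \code{"hydro_params"}.
#' @export
hydro_params <- function(coefficient = 0.027, exponent = 0.5) {
  if (!is.numeric(coefficient) || coefficient <= 0)
    stop("'coefficient' must be > 0")
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "hydro_params")
}

#' Theoretical random-coil hydrodynamic radius from molecular mass
#'
#' @param mass Molecular mass in Da (>= 0).
#' @param params \code{\link{hydro_params}}.
#' @return Hydrodynamic radius in Angstrom.
#' @examples
#' random_coil_rh(2819.27)  # 14.3 A
#' @export
random_coil_rh <- function(mass, params = hydro_params()) {
  if (any(mass < 0)) stop("'mass' must be >= 0")
  10 * params$coefficient * mass^params$exponent
}

#' Molecular mass implied by a random-coil hydrodynamic radius
#'
#' Exact inverse of \code{\link{random_coil_rh}}.
#'
#' @param rh Hydrodynamic radius in Angstrom (>= 0).
#' @param params \code{\link{hydro_params}}.
#' @return Mass in Da.
#' @export
mass_from_rh <- function(rh, params = hydro_params()) {
  if (any(rh < 0)) stop("'rh' must be >= 0")
  (rh / (10 * params$coefficient))^(1 / params$exponent)
}

#' Oligomer order from an estimated species mass
#'
#' Ratio of the estimated solution-species mass to the monomer mass, rounded
#' to the nearest integer (half away from zero) to give the oligomer order;
#' e.g. a ratio of 5.83 calls a hexamer.
#'
#' @param estimated_mass Estimated species mass in Da (> 0).
#' @param monomer_mass Monomer mass in Da (> 0).
#' @return List with \code{ratio} (numeric) and \code{order} (integer).
#' @examples
#' oligomer_order(16421.9, 2819.27)  # ratio 5.83 -> hexamer
#' @export
oligomer_order <- function(estimated_mass, monomer_mass) {
  if (estimated_mass <= 0 || monomer_mass <= 0)
    stop("masses must be > 0")
  ratio <- estimated_mass / monomer_mass
  # round half away from zero (base round() rounds half to even)
  ord <- as.integer(sign(ratio) * floor(abs(ratio) + 0.5))
  list(ratio = ratio, order = ord)
}

#' Read a single peptide sequence from a FASTA file
#'
#' @param path FASTA file path; the first record is used.
#' @param start_number,n_term_cap,c_term_cap Passed to
#'   \code{\link{peptide_sequence}}.
#' @return A \code{\link{peptide_sequence}}.
#' @export
read_fasta_peptide <- function(path, start_number = 1L,
                               n_term_cap = "free", c_term_cap = "free") {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (!length(recs)) stop("no sequences in FASTA file: ", path)
  peptide_sequence(as.character(recs[[1L]]), start_number = start_number,
                   n_term_cap = n_term_cap, c_term_cap = c_term_cap)
}
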