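#' @include decision.R
NULL

#' Construct an annotated nucleic-acid sequence
#'
#' Parses the compact oligo dialect used throughout this field's probe
#' tables: bases `A C G T U`, whitespace ignored, and a lowercase `m` prefix
#' marking the following residue as 2'-O-methyl (e.g. `"TTT CmUA CCA"`).
#' Unprefixed residues get the `sugar` default.
#'
#' @param x sequence string (or character vector of single bases).
#' @param sugar default sugar for unprefixed residues: `"deoxy"` (default),
#'   `"ribo"`, or `"2OMe"` for all-2'-OMe oligos.
#' @param name optional sequence name.
#' @return A [NucleicSequence-class].
#' @examples
#' nucleicSequence("UGG AGU GUG ACA AUG GUG UUU G", sugar = "ribo",
#'                 name = "miRNA122")
#' nucleicSequence("TTT CmUA CCA mUAG GGmU AAA ACC ACmU GAA")
#' @export
nucleicSequence <- function(x, sugar = c("deoxy", "ribo", "2OMe"),
                            name = "") {
  sugar <- match.arg(sugar)
  if (length(x) == 1L) x <- strsplit(gsub("[[:space:]]", "", x), "")[[1]]
  bases <- character(0)
  sugars <- character(0)
  i <- 1L
  while (i <= length(x)) {
    ch <- x[i]
    if (ch == "m") {
      if (i == length(x))
        stop("parse error: trailing 'm' with no base")
      bases <- c(bases, toupper(x[i + 1L]))
      sugars <- c(sugars, "2OMe")
      i <- i + 2L
    } else {
      bases <- c(bases, toupper(ch))
      sugars <- c(sugars, sugar)
      i <- i + 1L
    }
  }
  bad <- setdiff(unique(bases), .BASES)
  if (length(bad))
    stop("validation error: ambiguous or unknown base(s): ",
         paste(bad, collapse = ", "))
  new("NucleicSequence", bases = bases, sugars = sugars,
      name = as.character(name))
}

#' @describeIn nucleicSequence Render back to the `mU` dialect.
#' @param ... ignored.
#' @export
setMethod("as.character", "NucleicSequence", function(x, ...) {
  paste0(ifelse(x@sugars == "2OMe", "m", ""), x@bases, collapse = "")
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

#' Reverse complement of an annotated sequence
#'
#' Watson-Crick complement, reversed, emitted in the requested chemistry:
#' with `sugar = "deoxy"` (default) A complements to T, with `"ribo"` to U.
#' Applying `reverseComplement` twice with matching chemistry returns the
#' original base sequence.
#'
#' @param x a [NucleicSequence-class].
#' @param sugar output chemistry for the complement strand.
#' @param ... unused.
#' @return A [NucleicSequence-class].
#' @examples
#' m122 <- nucleicSequence("UGGAGUGUGACAAUGGUGUUUG", sugar = "ribo")
#' as.character(reverseComplement(m122))  # "CAAACACCATTGTCACACTCCA"
#' @export
setMethod("reverseComplement", "NucleicSequence",
          function(x, sugar = c("deoxy", "ribo", "2OMe"), ...) {
  sugar <- match.arg(sugar)
  if (!length(x@bases)) stop("validation error: empty sequence")
  comp <- unname(.COMPLEMENT[x@bases])
  if (sugar == "ribo") comp[comp == "T"] <- "U"
  new("NucleicSequence", bases = rev(comp),
      sugars = rep(sugar, length(comp)),
      name = if (nzchar(x@name)) paste0("revcomp(", x@name, ")") else "")
})

#' @rdname reverseComplement-NucleicSequence-method
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  reverseComplement(nucleicSequence(x), ...)
})
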