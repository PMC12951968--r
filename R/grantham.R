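# Grantham (1974) amino-acid substitution distances. Values quantify combined
# differences in composition, polarity and molecular volume; larger = more
# radical substitution. Residue order below is Grantham's original table order.

.grantham_aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                  "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

.grantham_upper <- c(
  110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
       102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
             98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
                  38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
                       58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
                            64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
                                109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
                                     135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
                                           21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
                                                22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
                                                     194,  83,  99, 143,  85, 160, 122,  36,  37,
                                                          174, 154, 139, 202, 154, 170, 196, 215,
                                                                24,  68,  32,  81,  40,  87, 115,
                                                                     46,  53,  61,  29, 101, 130,
                                                                          94,  23,  42, 142, 174,
                                                                              101,  56,  95, 110,
                                                                                    45, 160, 181,
                                                                                        126, 152,
                                                                                              67)

.grantham_build <- function() {
  m <- matrix(0, 20L, 20L, dimnames = list(.grantham_aa, .grantham_aa))
  k <- 1L
  for (i in 1:19) for (j in (i + 1L):20L) {
    m[i, j] <- .grantham_upper[k]
    m[j, i] <- .grantham_upper[k]
    k <- k + 1L
  }
  m
}

.grantham_env <- new.env(parent = emptyenv())

#' The embedded Grantham substitution matrix
#'
#' @return symmetric 20 x 20 numeric matrix of Grantham distances with
#'   one-letter amino-acid dimnames; diagonal zero.
#' @examples
#' grantham_matrix()["L", "R"]  # 102
#' @export
grantham_matrix <- function() {
  if (is.null(.grantham_env$m)) .grantham_env$m <- .grantham_build()
  .grantham_env$m
}

#' Grantham distance between two amino acids
#'
#' @param ref_aa,alt_aa one-letter amino-acid codes (vectorised).
#' @return numeric vector of distances.
#' @export
grantham_distance <- function(ref_aa, alt_aa) {
  m <- grantham_matrix()
  ref_aa <- toupper(ref_aa); alt_aa <- toupper(alt_aa)
  bad <- !(ref_aa %in% .grantham_aa) | !(alt_aa %in% .grantham_aa)
  if (any(bad))
    stop("unknown amino acid code(s): ",
         paste(unique(c(ref_aa[bad], alt_aa[bad])), collapse = ", "), call. = FALSE)
  m[cbind(ref_aa, alt_aa)]
}

#' Recompute calibration quantiles of the Grantham matrix
#'
#' The substitution-impact component uses two cut points (defaults 64 and
#' 109). This helper recomputes candidate median / upper-quartile calibrations
#' from the embedded matrix under two documented readings of "possible
#' scores": `"matrix_pairs"` uses the 190 unordered amino-acid pair distances;
#' `"snv_events"` restricts to substitutions reachable by a single nucleotide
#' change under the standard genetic code (one value per codon substitution
#' event), the relevant universe for single-nucleotide variant data.
#'
#' @param method which score universe to take quantiles over.
#' @return named numeric vector with elements `median` and `q75`.
#' @export
grantham_calibration <- function(method = c("matrix_pairs", "snv_events")) {
  method <- match.arg(method)
  m <- grantham_matrix()
  if (method == "matrix_pairs") {
    v <- m[upper.tri(m)]
  } else {
    code <- Biostrings::GENETIC_CODE
    bases <- c("T", "C", "A", "G")
    v <- numeric(0)
    for (cd in names(code)) {
      a1 <- code[[cd]]
      if (a1 == "*") next
      for (pos in 1:3) for (b in bases) {
        if (b == substr(cd, pos, pos)) next
        cd2 <- cd
        substr(cd2, pos, pos) <- b
        a2 <- code[[cd2]]
        if (a2 == "*" || a2 == a1) next
        v <- c(v, m[a1, a2])
      }
    }
  }
  c(median = unname(stats::median(v)),
    q75 = unname(stats::quantile(v, 0.75, names = FALSE)))
}
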