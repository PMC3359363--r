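#' The XynB xylanase 20-site case study table
#'
#' Feature table for 20 candidate C/S/T insertion sites between residues 64
#' and 206 of the catalytic domain of the XynB endo-1,4-beta xylanase from
#' *Dictyoglomus thermophilum* (UniProt P77853), each tested experimentally
#' for splicing of the *Thermus thermophilus* DnaE-1 intein.  For every site
#' the table carries the four native-site features: minimum C-alpha distance
#' to the active site (Angstrom), cassette SVM score, distance to the
#' nearest secondary structure/loop junction (residues; `Inf` encodes the
#' ">2" reporting bin), and conservation rank, plus the experimental
#' splicing outcome (11 of the 20 sites splice).
#'
#' @return data frame with 20 rows and columns `site` (e.g. `"S158"`),
#'   `position`, `residue`, `distance`, `svm_score`, `junction`,
#'   `conservation`, `splicing` (logical).
#' @examples
#' xynb <- xynb_sites()
#' sum(xynb$splicing)
#' @export
xynb_sites <- function() {
  df <- data.frame(
    site = c("C64", "S112", "T113", "S124", "T134", "S135", "T140",
             "T151", "T152", "S158", "T164", "S170", "T173", "S174",
             "T177", "S178", "T182", "T199", "T204", "C206"),
    distance = c(10.01, 6.74, 8.99, 10.58, 17.40, 17.22, 21.71,
                 9.71, 9.37, 8.15, 10.33, 12.06, 18.16, 17.45,
                 13.89, 16.44, 17.55, 11.61, 11.54, 6.43),
    svm_score = c(0.41, 0.11, 0.36, -1.34, 0.66, -1.13, -0.02,
                  -0.29, 0.19, 0.34, 0.21, -0.45, -1.47, -0.32,
                  -1.38, -0.01, -0.15, -0.60, -0.16, -0.55),
    junction = c(Inf, Inf, 2, 2, 1, 1, 2,
                 Inf, Inf, 2, 2, Inf, 1, 2,
                 1, 1, Inf, 1, Inf, Inf),
    conservation = c(0.55, 0.85, 0.34, 0.68, 0.30, 0.00, 0.81,
                     0.09, 0.43, 0.91, 0.96, 1.00, 0.49, 0.36,
                     0.32, 0.62, 0.77, 0.23, 0.51, 0.70),
    splicing = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                 FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                 FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  df$residue <- substr(df$site, 1L, 1L)
  df$position <- as.integer(substring(df$site, 2L))
  # packaged-table integrity: 20 C/S/T sites, 11 experimentally confirmed
  # splicers; a corrupted table must fail loudly, never load silently
  stopifnot(nrow(df) == 20L, sum(df$splicing) == 11L,
            all(df$residue %in% CST), !anyDuplicated(df$site))
  df[, c("site", "position", "residue", "distance", "svm_score",
         "junction", "conservation", "splicing")]
}
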