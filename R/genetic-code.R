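#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Fixed alphabetical order of the 64 DNA codons used for every wide table.
CODONS <- sort(names(Biostrings::GENETIC_CODE))
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

# Isotypes whose tRNAs are substrates of the heterodimeric ADAT2/ADAT3
# deaminase (wobble A34 -> inosine). Their codon boxes share the first two
# bases listed here; the inosine-read codons end C, T or A.
HETADAT_ISOTYPES <- c(
  Ala = "GC", Arg = "CG", Ile = "AT", Leu = "CT",
  Pro = "CC", Ser = "TC", Thr = "AC", Val = "GT"
)

#' The standard genetic code with codon annotations
#'
#' One row per DNA codon, annotated with the amino acid it encodes, its
#' third-base class (`nnA`/`nnC`/`nnG`/`nnT`), the degeneracy of its
#' synonymous family within the codon box sharing the first two bases, and
#' whether it belongs to a hetADAT (wobble-inosine) codon class. The eight
#' hetADAT tRNA isotypes (Ala, Arg, Ile, Leu, Pro, Ser, Thr, Val) carry A at
#' the anticodon wobble position; once edited to inosine the tRNA reads the
#' corresponding `nnC`, `nnT` and `nnA` codons.
#'
#' @return A tibble with columns `codon`, `aa` (one-letter, `*` for stop),
#'   `is_stop`, `third_base_class`, `degeneracy`, `hetadat_class`
#'   (`NA`, `"nnC"`, `"nnT"` or `"nnA"`) and `hetadat_isotype`.
#' @examples
#' codon_table()
#' @export
codon_table <- function() {
  aa <- unname(Biostrings::GENETIC_CODE[CODONS])
  first2 <- substr(CODONS, 1, 2)
  third <- substr(CODONS, 3, 3)
  degeneracy <- vapply(seq_along(CODONS), function(i) {
    box <- aa[first2 == first2[i]]
    sum(box == aa[i])
  }, integer(1))
  het_box <- match(first2, HETADAT_ISOTYPES)
  het_class <- ifelse(!is.na(het_box) & third %in% c("C", "T", "A"),
    paste0("nn", third), NA_character_
  )
  tibble::tibble(
    codon = CODONS,
    aa = aa,
    is_stop = CODONS %in% STOP_CODONS,
    third_base_class = paste0("nn", third),
    degeneracy = degeneracy,
    hetadat_class = het_class,
    hetadat_isotype = ifelse(is.na(het_class), NA_character_,
      names(HETADAT_ISOTYPES)[het_box]
    )
  )
}

#' Codons read by inosine-modified (hetADAT-substrate) tRNAs
#'
#' @param class One or more of `"nnC"`, `"nnT"`, `"nnA"`. Each class holds
#'   exactly eight codons, one per hetADAT isotype.
#' @return Character vector of codons.
#' @examples
#' hetadat_codons("nnC")
#' @export
hetadat_codons <- function(class = c("nnC", "nnT", "nnA")) {
  class <- match.arg(class, c("nnC", "nnT", "nnA"), several.ok = TRUE)
  tab <- codon_table()
  tab$codon[!is.na(tab$hetadat_class) & tab$hetadat_class %in% class]
}
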