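#' Marker panels for mammary epithelial cell types
#'
#' Returns the marker-gene panels used to gate mammary epithelial cell types
#' in single-nucleus RNA-seq of mouse mammary gland:
#' luminal alveolar (AV), luminal hormone-sensitive (HS), myoepithelial (ME),
#' plus the proliferating-cell and regulon feature lists whose co-expression
#' defines the PPBC-like (postpartum-breast-cancer-like) sub-population.
#'
#' The symbol `Bud1` in the proliferating panel is nonstandard but kept
#' verbatim from the source feature list; [annotate_cells()] warns and skips
#' any panel gene absent from a counts matrix.
#'
#' @return Named list of character vectors: `AV`, `HS`, `ME`, `proliferating`,
#'   `regulon`.
#' @examples
#' marker_panels()$HS
#' @export
marker_panels <- function() {
  list(
    AV = c("Mfge8", "Trf", "Csn3", "Wfdc18", "Ltf"),
    HS = c("Prlr", "Pgr", "Esr1", "Cited1", "Prom1"),
    ME = c("Krt17", "Krt14", "Krt5"),
    proliferating = c("Cenpe", "Ccna2", "Ccnb2", "Mcm6", "Ccnf", "Bud1"),
    regulon = c("Bclaf1", "Cux1", "E2f1", "E2f4", "Esr1", "Foxm1", "Gtf2b",
                "Max", "Myc", "Nfya", "Nr4a1", "Nrf1", "Smarca4", "Taf1")
  )
}
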