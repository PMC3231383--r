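#' Reference specimen inventory of the study garden
#'
#' The species inventory of the urban experimental garden the analysis was
#' designed around: 23 named species plus an unidentified group, 168 tree
#' specimens in total. Species with at least five identified specimens (the
#' bold subset, 10 species / 133 specimens) additionally enter the
#' individual-species classification task.
#'
#' @return A data.frame with columns `index`, `common_name`, `latin_name`,
#'   `habit` (`"coniferous"`/`"deciduous"`), `count`, and `species_task`
#'   (logical: member of the 10-species classification subset). The
#'   unidentified group appears as two rows (deciduous and coniferous) with
#'   `index = NA`.
#' @examples
#' sum(table1_fixture()$count)  # 168
#' @export
table1_fixture <- function() {
  sp <- data.frame(
    index = c(1:23, NA, NA),
    common_name = c(
      "Finnish Whitebeam", "Swedish Whitebeam", "European Rowan",
      "Common Whitebeam", "American Mountain-ash", "Pedunculate Oak",
      "Norway Maple", "Apple", "Hungarian Lilac", "Common Alder",
      "Camperdown Elm", "Crack Willow", "Colorado Blue Spruce",
      "Black Spruce", "White Fir", "Siberian Fir", "Balsam Fir",
      "Common Juniper", "European Yew", "Northern Whitecedar",
      "Common Douglas-fir", "Silver Birch", "Scots Pine",
      "Unidentified (deciduous)", "Unidentified (coniferous)"),
    latin_name = c(
      "Sorbus hybrida", "Sorbus intermedia", "Sorbus aucuparia",
      "Sorbus aria", "Sorbus americana", "Quercus robur",
      "Acer platanoides", "Malus domestica", "Syringa josikea",
      "Alnus glutinosa", "Ulmus glabra camperdownii", "Salix fragilis",
      "Picea pungens", "Picea mariana", "Abies concolor",
      "Abies sibirica", "Abies balsamea", "Juniperus communis",
      "Taxus baccata", "Thuja occidentalis", "Pseudotsuga menziesii",
      "Betula pendula", "Pinus sylvestris",
      "unidentified", "unidentified"),
    habit = c(
      rep("deciduous", 12), rep("coniferous", 9), "deciduous", "coniferous",
      "deciduous", "coniferous"),
    count = c(6L, 8L, 21L, 9L, 23L, 18L, 4L, 3L, 1L, 4L, 5L, 8L,
              5L, 4L, 2L, 30L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 5L, 2L),
    stringsAsFactors = FALSE)
  sp$species_task <- !is.na(sp$index) & sp$count >= 5L
  sp
}

#' Worked-example confusion matrix for the 10-species task
#'
#' The published error matrix of the best mixed feature quadruple (structural
#' features hq90 and Mean, spectral channels nearest 428 nm and 982 nm) on
#' the 133-specimen species task. Rows are predicted species, columns are
#' reference species. Used as an arithmetic fixture for
#' [confusion_summary()].
#'
#' @return A 10 x 10 integer matrix with species dimnames
#'   (`predicted` x `reference`).
#' @examples
#' confusion_summary(table5_fixture())$overall  # 83.5 after rounding
#' @export
table5_fixture <- function() {
  species <- c("Sorbus hybrida", "Sorbus intermedia", "Sorbus aucuparia",
               "Sorbus aria", "Sorbus americana", "Quercus robur",
               "Ulmus glabra camperdownii", "Salix fragilis",
               "Picea pungens", "Abies sibirica")
  m <- matrix(c(
    5, 1,  0, 0,  0,  0, 0, 0, 0,  1,
    0, 5,  2, 0,  0,  0, 0, 0, 0,  0,
    0, 1, 15, 3,  1,  0, 0, 0, 0,  0,
    0, 0,  3, 5,  0,  0, 0, 0, 0,  0,
    1, 0,  0, 0, 22,  0, 0, 0, 0,  0,
    0, 0,  0, 0,  0, 18, 0, 0, 0,  0,
    0, 0,  0, 0,  0,  0, 3, 0, 1,  0,
    0, 0,  0, 0,  0,  0, 2, 8, 1,  0,
    0, 0,  0, 1,  0,  0, 0, 0, 1,  0,
    0, 1,  1, 0,  0,  0, 0, 0, 2, 29),
    nrow = 10, byrow = TRUE,
    dimnames = list(predicted = species, reference = species))
  storage.mode(m) <- "integer"
  m
}
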