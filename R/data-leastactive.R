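#' Published binding scores of the least active fullerenes
#'
#' The printed summary table of the least active fullerene derivatives:
#' pristine C60 (`FD168`, the reference compound with the lowest binding
#' activity), C70, C80H2 and four lightly hydroxylated/carboxylated cages,
#' with their average binding scores (Bscore units). Used to reproduce the
#' published binding-activity differences against pristine C60 with
#' [deltaVsReference()].
#'
#' @format A data.frame with 7 rows and 3 columns: `id` (compound ID),
#'   `formula` (molecular formula / functional groups), `bscore` (average
#'   binding score).
#' @examples
#' av <- setNames(fdLeastActive$bscore, fdLeastActive$id)
#' deltaVsReference(av, "FD168")
#' @export
fdLeastActive <- data.frame(
  id = c("FD168", "FD50", "FD169", "FD160", "FD57", "FD61", "FD93"),
  formula = c("C60", "C70", "C80H2", "C60(OH)4", "C60-CH-COOH",
              "C60H34(OH)20", "C60H26(OH)24"),
  bscore = c(3938.3, 4224.3, 4398.5, 4192.2, 4412.7, 4725.1, 4735.3),
  stringsAsFactors = FALSE)
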