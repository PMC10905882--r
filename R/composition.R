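# Published catch-composition and study-accounting tables, shipped as
# plain CSV so the desk-scale arithmetic of the study is recomputable.

#' Manually-classified catch composition of the two field trials
#'
#' Species-level manual counts of both field trials (target mosquitoes,
#' non-target mosquito genera, and other insects), as inspected by a
#' trained entomologist.
#'
#' @param path CSV path; defaults to the table shipped with the
#'   package.
#' @return data frame with `trial`, `category` (`target`,
#'   `nontarget_mosquito`, `other_insect`), `genus`, `species`, `count`.
#' @export
read_trial_composition <- function(path = system.file(
  "extdata", "field_trial_composition.csv", package = "wingbeatr")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Study accounting quantities
#'
#' Sample-accounting scalars of the study: laboratory recordings before
#' and after cleaning, catch bags collected, and cycles excluded for
#' depredation or connectivity loss.
#'
#' @param path CSV path; defaults to the table shipped with the
#'   package.
#' @return named numeric vector.
#' @export
read_study_design <- function(path = system.file(
  "extdata", "study_design.csv", package = "wingbeatr")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

#' Summarise a catch composition table
#'
#' Per-trial (and combined) totals derived from the manual catch
#' composition: mosquitoes counted, target mosquitoes (*Aedes* +
#' *Culex*), total insects, and the target proportion of the catch.
#'
#' @param comp composition table from [read_trial_composition()].
#' @return data frame with one row per trial plus a `"combined"` row:
#'   `trial`, `mosquitoes`, `target`, `insects`,
#'   `target_proportion_pct`.
#' @export
composition_summary <- function(comp) {
  one <- function(df, label) {
    mosq <- sum(df$count[df$category %in% c("target", "nontarget_mosquito")])
    targ <- sum(df$count[df$category == "target"])
    tot <- sum(df$count)
    data.frame(
      trial = label, mosquitoes = mosq, target = targ, insects = tot,
      target_proportion_pct = 100 * targ / tot
    )
  }
  rows <- lapply(sort(unique(comp$trial)), function(tr) {
    one(comp[comp$trial == tr, , drop = FALSE], as.character(tr))
  })
  rbind(do.call(rbind, rows), one(comp, "combined"))
}

#' Data-cleaning rejection rate
#'
#' @param recorded number of recordings before cleaning.
#' @param valid number of recordings retained.
#' @return rejected percentage, `100 * (recorded - valid) / recorded`.
#' @export
cleaning_rejection_pct <- function(recorded, valid) {
  stopifnot(recorded > 0, valid >= 0, valid <= recorded)
  100 * (recorded - valid) / recorded
}
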