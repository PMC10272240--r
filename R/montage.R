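#' The fixed 14-electrode montage
#'
#' The consumer EEG headset targeted by this pipeline records from 14 scalp
#' sites of the international 10-20 system. Odd-numbered labels sit over the
#' left hemisphere (LH), even-numbered labels over the right (RH). For the
#' cortical-area factor the electrodes split into a frontal area
#' (FA: AF3, F7, F3, F4, F8, AF4, FC5, FC6) and a rear area
#' (RA: O1, O2, P7, P8, T7, T8). Seven homologous left-right pairs
#' (AF3|AF4, F3|F4, F7|F8, FC5|FC6, T7|T8, P7|P8, O1|O2) support
#' electrode-level hemispheric contrasts.
#'
#' @return An object of class `eeg_montage`: a list with
#'   `electrodes` (ordered character vector of 14 labels),
#'   `hemisphere_of` (named character vector, values `"LH"`/`"RH"`),
#'   `area_of` (named character vector, values `"FA"`/`"RA"`), and
#'   `homologous_pairs` (list of 7 `c(LH, RH)` label pairs).
#' @examples
#' m <- default_montage()
#' m$hemisphere_of[["AF3"]]  # "LH"
#' m$area_of[["O2"]]         # "RA"
#' @export
default_montage <- function() {
  electrodes <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                  "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  digit <- as.integer(sub("^[A-Za-z]+", "", electrodes))
  hemisphere_of <- ifelse(digit %% 2L == 1L, "LH", "RH")
  names(hemisphere_of) <- electrodes
  fa <- c("AF3", "F7", "F3", "F4", "F8", "AF4", "FC5", "FC6")
  area_of <- ifelse(electrodes %in% fa, "FA", "RA")
  names(area_of) <- electrodes
  homologous_pairs <- list(
    c("AF3", "AF4"), c("F3", "F4"), c("F7", "F8"), c("FC5", "FC6"),
    c("T7", "T8"), c("P7", "P8"), c("O1", "O2")
  )
  structure(
    list(electrodes = electrodes, hemisphere_of = hemisphere_of,
         area_of = area_of, homologous_pairs = homologous_pairs),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$electrodes), " electrodes\n", sep = "")
  cat("  LH:", paste(names(x$hemisphere_of)[x$hemisphere_of == "LH"], collapse = " "), "\n")
  cat("  RH:", paste(names(x$hemisphere_of)[x$hemisphere_of == "RH"], collapse = " "), "\n")
  cat("  FA:", paste(names(x$area_of)[x$area_of == "FA"], collapse = " "), "\n")
  cat("  RA:", paste(names(x$area_of)[x$area_of == "RA"], collapse = " "), "\n")
  invisible(x)
}
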