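#' Standard 20-channel montage and cognitive-system parcellation
#'
#' The analysis assumes a 20-electrode scalp montage grouped into six
#' cognitive systems: frontal (F), prefrontal (PF), central (C),
#' temporal (T), parietal (Pa) and occipital (O). Each electrode belongs
#' to exactly one system.
#'
#' @return `eeg_channels()` returns the 20 canonical channel labels in
#'   montage order. `system_parcellation()` returns a named list mapping
#'   system code to its channel labels.
#' @examples
#' system_parcellation()$PF
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "F7", "F8", "C3", "Cz", "C4",
    "T3", "T4", "T5", "T6", "P3", "Pz", "P4", "POz", "O1", "O2")
}

#' @rdname eeg_channels
#' @export
system_parcellation <- function() {
  list(
    F  = c("F3", "Fz", "F4", "F7", "F8"),
    PF = c("Fp1", "Fp2"),
    C  = c("C3", "Cz", "C4"),
    T  = c("T3", "T4", "T5", "T6"),
    Pa = c("P3", "Pz", "P4", "POz"),
    O  = c("O1", "O2")
  )
}

#' Look up the cognitive system of a channel
#'
#' @param channel character vector of channel labels.
#' @param parcellation a parcellation list as returned by
#'   [system_parcellation()].
#' @return character vector of system codes.
#' @export
channel_system <- function(channel, parcellation = system_parcellation()) {
  map <- rep(names(parcellation), lengths(parcellation))
  names(map) <- unlist(parcellation, use.names = FALSE)
  out <- unname(map[channel])
  if (anyNA(out)) {
    abort(paste0("channel(s) not in parcellation: ",
                 paste(channel[is.na(out)], collapse = ", ")))
  }
  out
}

#' Canonical EEG frequency bands
#'
#' Four analysis bands: theta 4--8 Hz, alpha 8--12 Hz, beta 12--35 Hz and
#' gamma 35--60 Hz.
#'
#' @param name optional band name; when given, a single band definition
#'   (list with `name`, `lo`, `hi`) is returned.
#' @return a tibble with columns `band`, `lo`, `hi`, or a single band list.
#' @examples
#' eeg_bands()
#' eeg_bands("gamma")
#' @export
eeg_bands <- function(name = NULL) {
  tab <- tibble(
    band = c("theta", "alpha", "beta", "gamma"),
    lo   = c(4, 8, 12, 35),
    hi   = c(8, 12, 35, 60)
  )
  if (is.null(name)) return(tab)
  row <- tab[tab$band == name, ]
  if (nrow(row) != 1) abort(paste0("unknown band: ", name))
  list(name = row$band, lo = row$lo, hi = row$hi)
}

#' Canonical names of the 96-dimensional feature space
#'
#' Twelve cognitive features (six per-system mental loads, situation
#' awareness, engagement, blink rate, asymmetry index, completion time and
#' mental workload) plus 84 functional features: per band, six within-system
#' strengths (named `"<band>:<system>"`) and fifteen between-system
#' communications (named `"<band>:<sys1>-<sys2>"`).
#'
#' @return character vector of length 96 in canonical order.
#' @examples
#' length(feature_names())
#' head(feature_names(), 15)
#' @export
feature_names <- function() {
  c(cognitive_feature_names(), functional_feature_names())
}

#' @rdname feature_names
#' @export
cognitive_feature_names <- function() {
  c(paste0("ML_", names(system_parcellation())),
    "SA", "E", "BR", "AI", "CT", "MW")
}

#' @rdname feature_names
#' @export
functional_feature_names <- function() {
  sys <- names(system_parcellation())
  pairs <- utils::combn(sys, 2, FUN = paste, collapse = "-")
  unlist(lapply(eeg_bands()$band, function(b) paste0(b, ":", c(sys, pairs))),
         use.names = FALSE)
}

#' Legal value range of each canonical feature
#'
#' Functional features are phase-locking averages in \[0, 1\]; BR, MW and E
#' are proportions in \[0, 1\]; AI is a normalized asymmetry in \[-1, 1\];
#' power-derived (ML, SA) and time (CT) features are non-negative.
#'
#' @return tibble with columns `feature`, `lo`, `hi`.
#' @export
feature_ranges <- function() {
  nm <- feature_names()
  lo <- rep(0, length(nm))
  hi <- rep(1, length(nm))
  power_like <- grepl("^ML_", nm) | nm %in% c("SA", "CT")
  hi[power_like] <- Inf
  lo[nm == "AI"] <- -1
  tibble(feature = nm, lo = lo, hi = hi)
}
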