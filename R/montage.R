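#' Electrode montage
#'
#' Thirty electrodes of the International 10-20 system with schematic 2-D
#' scalp coordinates (x: left-right, y: back-front, unit head radius). The
#' first twelve sites are the frontal set used for global field power:
#' Fp1, Fpz, Fp2, F7, F3, Fz, F4, F8, Fc5, Fc1, Fc2, Fc6.
#'
#' @return Tibble with columns `channel`, `x`, `y`, `frontal`, `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`).
#' @export
electrode_positions <- function() {
  tibble::tibble(
    channel = c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "Fc5", "Fc1", "Fc2", "Fc6",
                "T7", "C3", "Cz", "C4", "T8",
                "Cp5", "Cp1", "Cp2", "Cp6",
                "P7", "P3", "Pz", "P4", "P8",
                "POz", "O1", "Oz", "O2"),
    x = c(-0.31, 0, 0.31, -0.81, -0.45, 0, 0.45, 0.81,
          -0.67, -0.25, 0.25, 0.67,
          -1, -0.5, 0, 0.5, 1,
          -0.67, -0.25, 0.25, 0.67,
          -0.81, -0.45, 0, 0.45, 0.81,
          0, -0.31, 0, 0.31),
    y = c(0.95, 1, 0.95, 0.59, 0.55, 0.5, 0.55, 0.59,
          0.27, 0.25, 0.25, 0.27,
          0, 0, 0, 0, 0,
          -0.27, -0.25, -0.25, -0.27,
          -0.59, -0.55, -0.5, -0.55, -0.59,
          -0.75, -0.95, -1, -0.95),
    frontal = c(rep(TRUE, 12), rep(FALSE, 18)),
    hemisphere = dplyr::case_when(x < 0 ~ "left", x > 0 ~ "right",
                                  TRUE ~ "midline")
  )
}

# Frontal electrode labels (the GFP electrode set).
frontal_channels <- function() electrode_positions()$channel[1:12]

# Left/right frontal pairs used by the pleasantness index.
left_frontal_channels <- function() c("Fp1", "F7", "F3", "Fc5", "Fc1")
right_frontal_channels <- function() c("Fp2", "F8", "F4", "Fc6", "Fc2")
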