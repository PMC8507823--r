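#' Render the five standard weekly-series figures
#'
#' Writes PNG figures mirroring the study's figure shapes:
#' participants by community (mental-health community curves scaled by
#' `display_factor` for visibility, as recorded in the legend),
#' posting frequency by community, emotion by community, and posting
#' frequency and emotion by MH/NMH cohort. Optional vertical event
#' markers come from an annotation table.
#'
#' @param community_series,cohort_series [weekly_series()] tables.
#' @param out_dir Output directory for the figure files.
#' @param annotations Optional data.frame (week, label) of event
#'   markers.
#' @param display_factor Display multiplier for MH-community
#'   participant curves (presentation only).
#' @return Character vector of the five file paths, invisibly.
#' @export
plot_series <- function(community_series, cohort_series, out_dir,
                        annotations = NULL, display_factor = 30) {
  if (!nrow(community_series) || !nrow(cohort_series))
    stop("cannot plot empty weekly series")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comm <- data.table::as.data.table(community_series)
  coh <- data.table::as.data.table(cohort_series)

  draw <- function(file, d, col, ylab, main, scale_keys = NULL) {
    keys <- unique(d$key)
    png(file.path(out_dir, file), width = 900, height = 540)
    on.exit(dev.off())
    wide <- data.table::dcast(d, week ~ key, value.var = col)
    mat <- as.matrix(wide[, -1L])
    leg <- colnames(mat)
    if (!is.null(scale_keys)) {
      sc <- leg %in% scale_keys
      mat[, sc] <- mat[, sc] * display_factor
      leg[sc] <- paste0(leg[sc], " (x", display_factor, ")")
    }
    if (!any(is.finite(mat))) mat[] <- 0   # e.g. unscored corpora
    matplot(wide$week, mat, type = "l", lty = 1, lwd = 2,
            col = seq_len(ncol(mat)), xlab = "week", ylab = ylab,
            main = main)
    if (!is.null(annotations) && nrow(annotations)) {
      abline(v = annotations$week, col = "grey70", lty = 3)
      mtext(annotations$label, side = 3, at = annotations$week,
            cex = 0.5, las = 0, line = 0.1)
    }
    legend("topright", legend = leg, col = seq_len(ncol(mat)),
           lty = 1, lwd = 2, bty = "n", cex = 0.8)
    file.path(out_dir, file)
  }

  files <- c(
    draw("participants_by_community.png", comm, "n_participants",
         "weekly active participants", "Weekly participants by community",
         scale_keys = MH_COMMUNITIES),
    draw("frequency_by_community.png", comm, "posts_per_participant",
         "posts/comments per participant",
         "Weekly posting frequency by community"),
    draw("emotion_by_community.png", comm, "mean_compound",
         "compound negative emotion", "Weekly emotion by community"),
    draw("frequency_by_cohort.png", coh, "posts_per_participant",
         "posts/comments per participant",
         "Weekly posting frequency by cohort"),
    draw("emotion_by_cohort.png", coh, "mean_compound",
         "compound negative emotion", "Weekly emotion by cohort"))
  invisible(files)
}
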