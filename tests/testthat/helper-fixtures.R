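# A 46-record cohort whose categorical margins re-enter the published
# baseline table: 26 CLNM-negative / 20 CLNM-positive, with per-stratum
# cT / cN / cStage counts assigned independently by position (the summary
# works on margins, so the joint assignment is immaterial).
tiny_table1_fixture <- function() {
  fill <- function(levels, counts) rep(levels, counts)
  neg <- data.frame(
    c_t = fill(c("T1", "T2", "T3", "T4"), c(6, 11, 6, 3)),
    c_n = fill(c("N0", "N1", "N2", "N3"), c(19, 3, 3, 1)),
    c_stage = fill(c("I", "II", "III", "IV"), c(6, 7, 8, 5)),
    clnm = 0L, stringsAsFactors = FALSE)
  pos <- data.frame(
    c_t = fill(c("T1", "T2", "T3", "T4"), c(2, 5, 10, 3)),
    c_n = fill(c("N0", "N1", "N2", "N3"), c(12, 2, 5, 1)),
    c_stage = fill(c("I", "II", "III", "IV"), c(2, 6, 5, 7)),
    clnm = 1L, stringsAsFactors = FALSE)
  df <- rbind(neg, pos)
  df$patient_id <- sprintf("F%02d", seq_len(nrow(df)))
  df$p_doi_mm <- seq(2, 20, length.out = nrow(df))
  df$us_doi_mm <- NA_real_
  df$mr_doi_mm <- NA_real_
  df[, c("patient_id", "p_doi_mm", "us_doi_mm", "mr_doi_mm",
         "clnm", "c_t", "c_n", "c_stage")]
}

# Published per-stratum percentages of that table, for full reconstruction
# checks (variable, level, stratum, percent).
table1_expected_percent <- function() {
  rbind(
    data.frame(variable = "c_t", level = c("T1", "T2", "T3", "T4"),
               stratum = "total", percent = c(17.4, 34.8, 34.8, 13.0)),
    data.frame(variable = "c_t", level = c("T1", "T2", "T3", "T4"),
               stratum = "clnm_negative", percent = c(23.1, 42.3, 23.1, 11.5)),
    data.frame(variable = "c_t", level = c("T1", "T2", "T3", "T4"),
               stratum = "clnm_positive", percent = c(10.0, 25.0, 50.0, 15.0)),
    data.frame(variable = "c_n", level = c("N0", "N1", "N2", "N3"),
               stratum = "total", percent = c(67.4, 10.9, 17.4, 4.3)),
    data.frame(variable = "c_n", level = c("N0", "N1", "N2", "N3"),
               stratum = "clnm_negative", percent = c(73.1, 11.5, 11.5, 3.8)),
    data.frame(variable = "c_n", level = c("N0", "N1", "N2", "N3"),
               stratum = "clnm_positive", percent = c(60.0, 10.0, 25.0, 5.0)),
    data.frame(variable = "c_stage", level = c("I", "II", "III", "IV"),
               stratum = "total", percent = c(17.4, 28.3, 28.3, 26.1)),
    data.frame(variable = "c_stage", level = c("I", "II", "III", "IV"),
               stratum = "clnm_negative", percent = c(23.1, 26.9, 30.8, 19.2)),
    data.frame(variable = "c_stage", level = c("I", "II", "III", "IV"),
               stratum = "clnm_positive", percent = c(10.0, 30.0, 25.0, 35.0))
  )
}
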