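# Published reference values for the line-comparison table shipped as
# inst/extdata/table1_traits.csv: the printed 95% drift CI, the printed
# D_y, whether the printed D_y was bold (exceeds drift), and whether the
# row's D_y is recomputable from the printed group summaries (some printed
# rows were evidently computed from unpublished family-level data and are
# excluded from D_y comparisons).
table1_reference <- function() {
  df <- read.csv(text = '
trait_name,experiment,ci,dy,bold,dy_reproducible
Home Cage Activity,1,1.26,1.54,TRUE,TRUE
Hits,1,1.29,1.30,TRUE,FALSE
Hits latency,1,1.21,-1.17,FALSE,FALSE
FA (V1),1.1,1.20,1.82,TRUE,TRUE
FA (V2),1.2,1.25,1.63,TRUE,FALSE
FA latency (V1),1.1,1.16,-2.06,TRUE,TRUE
FA latency (V2),1.2,1.21,-1.27,TRUE,FALSE
Home Cage Activity,2,1.22,0.97,FALSE,TRUE
Y-maze arm entries,2,1.11,1.30,TRUE,TRUE
Rotarod latency (s),2,1.13,-0.77,FALSE,TRUE
Hits,2,1.25,1.15,FALSE,TRUE
AMPH on Hits,2,1.18,-2.80,TRUE,FALSE
FA,2,1.16,1.62,TRUE,TRUE
AMPH on FA,2,1.18,-0.68,FALSE,FALSE
AMPH on FA latency,2,1.18,1.17,FALSE,FALSE
Home Cage Activity,3,1.31,1.38,TRUE,FALSE
Hits,3,1.33,4.92,TRUE,TRUE
AMPH on Hits,3,1.26,-1.93,TRUE,FALSE
Hits latency,3,1.25,-3.53,TRUE,FALSE
AMPH on Hits latency,3,1.26,1.66,TRUE,FALSE
FA,3,1.25,2.44,TRUE,TRUE
FA latency,3,1.21,-2.03,TRUE,TRUE
', stringsAsFactors = FALSE)
  df$experiment <- as.character(df$experiment)
  df
}

table1_fixture <- function() {
  read_trait_table(system.file("extdata", "table1_traits.csv",
                               package = "linedrift"))
}

colony_F <- 0.06217
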