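# Published per-class landscape index table for the six Xishuangbanna
# land-use classes, 1996-2017 (C fragmentation, S separation, D fractal
# dimension, E disturbance, F vulnerability, R loss). Two cells are
# internally inconsistent with the index formulas (tea 1996 E; forest 2017
# R) and are flagged here rather than corrected.
reference_class_table <- function() {
  tab <- read.table(text = "
forest 1996 0.004 0.037 1.252 0.263 0.10 0.026
forest 2003 0.004 0.039 1.250 0.264 0.10 0.026
forest 2010 0.009 0.063 0.939 0.211 0.10 0.021
forest 2017 0.008 0.060 1.268 0.275 0.10 0.021
rubber 1996 0.047 0.258 1.388 0.379 0.28 0.106
rubber 2003 0.049 0.268 1.375 0.380 0.28 0.106
rubber 2010 0.015 0.108 0.990 0.238 0.28 0.067
rubber 2017 0.020 0.135 1.323 0.315 0.28 0.088
tea 1996 0.205 0.784 1.329 0.903 0.24 0.217
tea 2003 0.123 0.661 1.403 0.540 0.24 0.130
tea 2010 0.112 0.631 1.330 0.511 0.24 0.123
tea 2017 0.064 0.436 1.358 0.434 0.24 0.104
cultivated 1996 0.115 0.768 1.376 0.563 0.14 0.079
cultivated 2003 0.072 0.724 1.285 0.510 0.14 0.072
cultivated 2010 0.049 0.504 1.286 0.433 0.14 0.061
cultivated 2017 0.064 0.456 1.352 0.439 0.14 0.062
builtup 1996 0.082 1.387 1.253 0.708 0.05 0.035
builtup 2003 0.169 2.030 1.299 0.953 0.05 0.048
builtup 2010 0.085 2.271 1.159 0.956 0.05 0.048
builtup 2017 0.146 1.723 1.311 0.852 0.05 0.043
water 1996 0.156 2.712 1.251 1.142 0.19 0.217
water 2003 0.622 2.715 1.339 1.393 0.19 0.265
water 2010 0.093 2.769 1.188 1.115 0.19 0.212
water 2017 0.111 2.502 1.222 1.051 0.19 0.200
", col.names = c("class", "year", "C", "S", "D", "E", "F", "R"))
  tab$E_consistent <- !(tab$class == "tea" & tab$year == 1996)
  tab$R_consistent <- !(tab$class == "forest" & tab$year == 2017)
  tab
}
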