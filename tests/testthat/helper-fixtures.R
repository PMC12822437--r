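# Shared synthetic fixtures (built in code; no real gene sequences).

# A synthetic 245-nt dCAPS-style amplicon carrying exactly one RsaI site
# (GTAC) placed so digestion yields 110 + 135 nt fragments.
make_template <- function(seed = 1, len = 245, site_at = 109) {
  set.seed(seed)
  repeat {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    chars[site_at:(site_at + 3)] <- c("G", "T", "A", "C")
    s <- paste(chars, collapse = "")
    hits <- gregexpr("GTAC", s, fixed = TRUE)[[1]]
    if (length(hits) == 1 && hits[1] == site_at) return(s)
  }
}
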