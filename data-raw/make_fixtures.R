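# Regenerates the packaged fixture files under inst/extdata from the
# in-code network definitions. Run from the package root:
#   Rscript data-raw/make_fixtures.R
devtools::load_all(".", quiet = TRUE)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

write_network(cholesterol_pkn(),
              "inst/extdata/cholesterol_pkn.sif",
              "inst/extdata/cholesterol_pkn_metadata.csv")
write_network(toy_pkn(),
              "inst/extdata/toy_pkn.sif",
              "inst/extdata/toy_pkn_metadata.csv")
write.csv(default_conditions(), "inst/extdata/conditions.csv",
          row.names = FALSE)
write.csv(toy_conditions(), "inst/extdata/toy_conditions.csv",
          row.names = FALSE)

# Reference monoisotopic masses for exact-mass ion annotation. HMDB-style
# neutral masses for a few endogenous metabolites plus the study drugs
# (stored neutral; the matcher subtracts a proton or adds fluoride).
proton <- 1.007276466
ref <- rbind(
  data.frame(metabolite = "T0901317", monoisotopic_mass = 480.031699 + proton),
  data.frame(metabolite = "GW3965", monoisotopic_mass = 580.1863299 + proton),
  data.frame(metabolite = "hydroxy-GW3965",
             monoisotopic_mass = 596.181546 + proton),
  data.frame(metabolite = "hydroxy-atorvastatin",
             monoisotopic_mass = 573.240091 + proton),
  data.frame(metabolite = "atorvastatin lactone",
             monoisotopic_mass = 539.234611 + proton),
  data.frame(metabolite = "mevalonate", monoisotopic_mass = 148.073559),
  data.frame(metabolite = "HMG-CoA", monoisotopic_mass = 911.124494),
  data.frame(metabolite = "acetyl-CoA", monoisotopic_mass = 809.125846),
  data.frame(metabolite = "cholesterol", monoisotopic_mass = 386.354866)
)
write.csv(ref, "inst/extdata/reference_masses.csv", row.names = FALSE)
cat("fixtures written\n")
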