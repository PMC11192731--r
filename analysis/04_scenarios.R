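#!/usr/bin/env Rscript
# Comparative statics: inequality and polarization can move in opposite
# directions. Two deterministic scenario pairs illustrate the mechanism and
# their indicator changes are tabulated under results/.

suppressPackageStartupMessages(library(lifespanineq))

indicators <- function(lt) {
  d <- to_distribution(lt)
  c(le = d$mu, mld = mld(d), gini = gini(d), variance = lifespan_variance(d),
    rder_25 = rel_der(d, 0.25), rder_1 = rel_der(d, 1))
}

rows <- list()
for (nm in c("adult_concentration", "infant_stagnation")) {
  pair <- make_scenario_pair(nm)
  before <- indicators(pair$before)
  after <- indicators(pair$after)
  rows[[nm]] <- data.frame(scenario = nm, indicator = names(before),
                           before = unname(before), after = unname(after),
                           direction = ifelse(after > before, "up", "down"))
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/scenario_comparative_statics.csv",
                 row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)

cat("\nReading the table:\n")
cat("- adult_concentration: concentrating old-age deaths around the modal\n",
  "  interval lowers MLD (less spread) yet raises relative polarization\n",
  "  (the old-age pole gains mass, strengthening identification).\n", sep = "")
cat("- infant_stagnation: adult progress with stagnant infant mortality\n",
  "  widens the gap between the infant and adult poles: inequality and\n",
  "  polarization rise together.\n", sep = "")
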