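#!/usr/bin/env Rscript
# Stage 4: post-estimation on the fitted part-worths — range-method
# relative importance (total and by treatment group), base-case preference
# shares, and the one-attribute-at-a-time sensitivity table. Writes
# results/{importance,shares,sensitivity}.csv.

library(hbchoice)

schema <- build_default_schema()
betas_df <- read.csv("results/betas.csv")
B <- as.matrix(betas_df[, grep("^b\\d+$", names(betas_df))])
rownames(B) <- betas_df$respondent_id

imp <- relative_importance(B, schema)
print(imp)
imp_table <- data.frame(attribute = names(imp$aggregate),
                        total = unname(imp$aggregate))
for (g in sort(unique(betas_df$group))) {
  imp_table[[make.names(g)]] <- relative_importance(
    B[betas_df$group == g, , drop = FALSE], schema)$aggregate
}
write.csv(imp_table, "results/importance.csv", row.names = FALSE)

# base cases: middle level everywhere, cost $50 (A) vs $100 (B)
base_a <- c(efficacy = "85 %", bone_risk = "7 %", kidney_risk = "10 %",
            patients_treated = "200,000", years_market = "4 years",
            cost = "$50")
base_b <- replace(base_a, "cost", "$100")

shares <- preference_shares(B, list(A = base_a, B = base_b), schema)
cat(sprintf("Base-case shares: A %.1f%% vs B %.1f%%\n",
            shares$aggregate[["A"]], shares$aggregate[["B"]]))
write.csv(data.frame(product = names(shares$aggregate),
                     share_pct = unname(shares$aggregate)),
          "results/shares.csv", row.names = FALSE)

sens <- sensitivity_analysis(B, base_a, base_b, schema)
ka <- sens[sens$product == "A" & sens$attribute == "kidney_risk", ]
cat("Flexing kidney risk of product A:\n")
print(ka[, c("level_label", "share_a")], row.names = FALSE)
write.csv(sens, "results/sensitivity.csv", row.names = FALSE)
cat("Wrote results/importance.csv, results/shares.csv, results/sensitivity.csv\n")
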