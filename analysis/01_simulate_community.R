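#!/usr/bin/env Rscript
# Stage 1: generate the synthetic defined-community study.
#
# Emulates the study design this pipeline targets: a 64-strain community
# with a known phylogeny, cultured with mucin carriers over 6 passages in
# biological triplicate (technical triplicates per tube), plus a no-carrier
# control. Three causal KO families with effect size 2 drive true
# carrier/supernatant preference on top of a Brownian lineage effect.
# All downstream stages read only the files written here.

suppressMessages(library(carrierscan))

run_dir <- "results/study_run"
dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20230614

tree <- simulate_tree(64, seed)
geno <- simulate_genotypes(tree, n_kos = 2000, presence_rate = 0.5,
                           seed = seed + 1)
causal <- c("K00441", "K00007", "K01234")
colnames(geno$bitscore)[1:3] <- causal
colnames(geno$presence)[1:3] <- causal
names(geno$threshold)[1:3] <- causal

trait <- simulate_phenotype(tree, geno, causal, beta = 2, bm_sigma2 = 1,
                            noise_sd = 0.1, seed = seed + 2)

design <- rbind(carrier_design(),
                expand.grid(condition = "no-carrier", passage = 1:6,
                            bio_rep = 1:3, tech_rep = 1:3,
                            stringsAsFactors = FALSE))
tab <- simulate_abundance(trait, design, noise_sd = 0.1, seed = seed + 3)

# taxonomy: three phylogenetically coherent clades cut from the tree
cl <- cutree(hclust(as.dist(ape::cophenetic.phylo(tree)), "average"), k = 3)
taxonomy <- data.frame(strain_id = names(cl),
                       phylum = c("Firmicutes_A", "Bacteroidota",
                                  "Firmicutes_C")[cl])

# gene neighborhoods with the anchor/partner colocalization planted
partners <- sprintf("K%05d", 10001:10004)
ann <- simulate_annotations(n_genomes = 50, genes_per_genome = 200,
                            ko_pool = 2000, partner_kos = partners,
                            colocal_prob = 1, seed = seed + 4)

# BGC complements with 8 planted signature groups
bgcs <- simulate_bgcs(tree$tip.label, n_groups = 8, kos_per_group = 6,
                      presence_prob = 0.6, noise_kos = 1, seed = seed + 5)

ape::write.tree(tree, file.path(run_dir, "tree.nwk"))
write_abundance_table(tab, file.path(run_dir, "abundance_raw.tsv"))
write_genotypes(geno, file.path(run_dir, "genotypes.tsv"))
write.table(data.frame(strain_id = names(trait), trait = unname(trait)),
            file.path(run_dir, "true_trait.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(taxonomy, file.path(run_dir, "taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_annotation(ann, file.path(run_dir, "annotations.tsv"))
flat <- bgcs[, c("bgc_id", "genome", "contig", "start", "end", "true_group")]
flat$kos <- vapply(bgcs$kos, paste, "", collapse = ",")
write.table(flat, file.path(run_dir, "bgcs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulated ", length(tree$tip.label), " strains, ",
        nrow(tab$samples), " sample libraries, ",
        ncol(geno$bitscore), " KO families, ",
        nrow(ann), " annotated genes, ", nrow(bgcs), " BGCs")
message("planted causal KOs: ", paste(causal, collapse = ", "))
message("outputs in ", run_dir)
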