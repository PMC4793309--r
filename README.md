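# sitefish

Structure-based inverse target fishing in R: given a protein–ligand complex,
find other proteins whose local residue arrangements could bind the same
ligand, gate the matches geometrically, rank them thermodynamically, and
summarize the resulting target set.

`sitefish` is aimed at structural bioinformaticians who have one or more
solved complexes of a small molecule (the motivating case is aspirin, with
five usable complexes) and want a transparent, fully seeded re-implementation
of the pocket-similarity funnel:

1. **Binding-site definition** — residues with a heavy atom within 5 Å of
   the ligand (`extract_site()`).
2. **Contact-matrix search** — for each database structure, enumerate
   residue combinations compatible with the site under BLOSUM62
   (score ≥ 1) and score them by the contact matrix average deviation

   CMAD = mean over pairs i<j of | d_q(i,j) − d_c(i,j) |,

   then superpose survivors by the Kabsch algorithm and rank by an
   empirical P-value; E-value = P × database size, significant at
   E < 0.01 (`site_search()`).
3. **Pose gate** — rigid transplant of the query ligand by the match
   transform, accepted iff no clash below 2.2 Å and at least 3 contacts
   within 4.5 Å (`transplant_pose()`, `steric_screen()`).
4. **Free-energy filter** — ΔG = G_complex − G_receptor − G_ligand − TΔS
   with a fixed entropy correction TΔS = ΔH + RT·ln K = 4.728 kcal/mol
   derived from the experimental aspirin–phospholipase A2 binding constant
   K = 1.56×10⁵ M⁻¹; targets kept at ΔG < 0
   (`entropy_from_constant()`, `apply_entropy_and_filter()`).

Downstream: pocket composition and acetylation-candidate statistics
(`composition()`, `acetylation_screen()`), a structural-similarity network
with edges at aligned-Cα RMSD < 4 Å (`build_network()`), and hypergeometric
pathway over-representation from a local GMT annotation (`enrich()`).

A synthetic-structure module (`make_decoy()`, `plant_site()`,
`make_benchmark()`) generates decoy proteins with planted, noised, mutated
copies of a query pocket, so sensitivity and specificity of every stage are
measurable with known ground truth and no downloads. See the methods
vignette (`vignettes/sitefish-methods.Rmd`) for the model, parameter
defaults, and design rationale.

## Worked example

```r
library(sitefish)

## entropy correction from the binding constant (printed RT ln K)
entropy_from_constant(-2.327, rt_ln_k = 7.055)
#> [1] 4.728

## the packaged putative-target table: classification and summary
tab  <- read_target_table(system.file("extdata", "table1_targets.tsv",
                                      package = "sitefish"))
summ <- classify_and_summarize(tab)
summ
#> <TargetSummary: 23 targets (9 primary, 14 new); dG range [-33.0, -6.0] kcal/mol>
sprintf("new targets: %d, mean dG(new) = %.1f kcal/mol", summ$n_new, summ$mean_dg_new)
#> "new targets: 14, mean dG(new) = -18.4 kcal/mol"

## a synthetic query complex and a seeded end-to-end run
qc <- make_query_complex(42)
qc$site
#> <BindingSite QRY_42_LIG: 17 residues within 5.0 A of LIG>

cfg <- pipeline_config(query_seed = 42, seed = 11,
                       benchmark = list(n_planted = 5, n_decoys = 20,
                                        noise_sigma = 0.3,
                                        n_substitutions = 1, n_res = 80),
                       n_null = 5000, null_decoys = 6,
                       out_dir = tempfile("demo_"))
rep <- run_pipeline(cfg)
rep
#> <StageReport: db 25 -> hits 5 -> gate 5 -> dG<0 4>
str(rep$recall)
#> List of 3
#>  $ search         : num 1
#>  $ final          : num 0.8
#>  $ false_positives: int 0
```

Reading the output: all 5 planted pockets are found by the contact-matrix
search among 25 structures and pass the pose gate; 4 clear the ΔG < 0
filter (final recall 0.8 at this small demo scale; at the default benchmark
scale of 10 planted among 100 decoys recall is ≥ 0.9), with zero decoys
surviving to the target list. Per-stage tables (hit list, screen results,
energies, pocket stats, network edges) are written under `cfg$out_dir`.

A thin command-line wrapper is installed with the package
(`inst/scripts/sitefish`): `sitefish run --config pipeline.yaml` and
`sitefish report --targets targets.tsv --out dir`.

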