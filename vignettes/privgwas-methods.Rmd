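---
title: "Methods: privacy-preserving stacked-ridge GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: privacy-preserving stacked-ridge GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The statistical model

privgwas tests quantitative-trait associations under the whole-genome
regression view of the linear mixed model. For $N$ samples, $M$ SNPs coded
as alternate-allele dosages $x \in \{0,1,2\}$, covariates $Z \in
\mathbb{R}^{N\times C}$ and a phenotype $y$:

$$ y = \beta_{\mathrm{test}}\, x_{\mathrm{test}} + Z\alpha + X\beta + e,
\qquad e \sim \mathcal{N}(0, \sigma_e^2 I), $$

where $X\beta$ is the polygenic background. Rather than estimating variance
components through the kinship matrix, the polygenic term is absorbed by a
cross-validated *stacked ridge* predictor $\hat y$ (the REGENIE lineage),
and each SNP is scored against the polygenic-adjusted residual:

$$ \chi^2 = \frac{\left(\tilde{x}^\top (\tilde{y} - \hat{y})\right)^2}
  {\hat\sigma_e^2\; \tilde{x}^\top \tilde{x}}, \qquad
  \hat\sigma_e^2 = \frac{\lVert \tilde y - \hat y \rVert^2}{N - C_1}, $$

with one degree of freedom and two-sided p-values from the $\chi^2_1$
survival function. Tildes denote standardization plus projection onto the
null space of the intercept-augmented covariates $Z_1 = [Z \mid 1]$
($C_1 = C + 1$ columns, the projector's true rank, which is also the
degrees-of-freedom correction; the package uses the projector rank rather
than guessing whether "covariates" includes the intercept).

## Stacked ridge regression

*Level 0.* The projected genotype matrix is cut into $B$ vertical blocks.
For a grid of $R$ penalties (default $R=5$)

$$ h_r = \frac{0.01\,(R-1) + 0.98\,(r-1)}{R-1}, \qquad
   \lambda_r = \frac{M\,(1-h_r^2)}{h_r^2}, $$

every (block, penalty) pair yields a ridge predictor, fitted under $K$-fold
cross-validation (default $K=5$) so that fold $k$'s predictions come from
coefficients estimated without fold $k$. The out-of-fold predictions form a
feature matrix $W \in \mathbb{R}^{N \times BR}$ (column order block-major).

*Level 1.* A second ridge fit of $\tilde y$ on $W$ with penalties
$\omega_r = (BR/M)\lambda_r$, again per fold:
$\hat\eta_{(k-1,r)} = (W_{k-1}^\top W_{k-1} + \omega_r I)^{-1} W_{k-1}^\top
\tilde y_{k-1}$. The grid index $r^*$ minimizes the summed out-of-fold
residual sum of squares; ties break toward the smallest $r$ (a deterministic
rule the selection needs but that is otherwise arbitrary). The global
predictor stitches $\hat y_k = W_k \hat\eta_{(k-1,r^*)}$ together.

Defaults $K=5$, $R=5$ and Level-0 blocks of 1000 SNPs are the conventions
this grid parameterization presupposes; all are exposed in `gwas_config()`.
The fold-exclusion subscripts are treated as $K$-fold cross-validation
throughout; chromosome-aware leave-one-chromosome-out is out of scope.

## Quality control and standardization

QC runs on pooled genotype-class counts only (hom-ref / het / hom-alt /
missing per SNP). Defaults, with their boundary semantics taken literally:

* missing rate (over all pooled samples) *exceeding* 0.1 fails;
* minor allele frequency (over called genotypes) must be *strictly greater*
  than 0.05;
* the 1-df Hardy–Weinberg goodness-of-fit statistic must not exceed
  23.928, the $\chi^2_1$ quantile at $p = 10^{-6}$. The printed pairing of a
  $\chi^2$ threshold with that p-value identifies the test as the plain
  goodness-of-fit statistic, not an exact test.

Monomorphic SNPs get statistic 0 plus a flag (and fail the MAF filter
anyway). Post-QC residual missing dosages are mean-imputed per SNP — the
standard fallback when no imputation pipeline is in scope — and
standardization uses population (divide-by-$n$) moments, because those are
exactly recoverable from pooled counts: the imputed-column mean equals the
called-genotype mean $2\hat p$ and the second moment adds $m^2$ per imputed
entry. The same masked-sum machinery pools $\sum y$ and $\sum y^2$ for the
phenotype scale.

# The distributed protocol

$P$ cohorts hold horizontal slices $(X_p, Z_p, y_p)$; a coordinating server
is honest-but-curious and non-colluding. All node-side randomness derives
from one shared seed the server never sees, via hierarchical label-path
derivation (`derive_seed()`), so nodes agree on every key without
communication. Public quantities: $N$, $M$, $C$, $B$, the grid, and the
final $\chi^2$ values.

## Masked aggregation

Sums of per-node arrays (QC counts, phenotype moments) travel as
$x_p + r_p$ with seed-derived masks $r_p$; the server returns
$\sum_p (x_p + r_p)$ and nodes subtract the known $\sum_p r_p$. Integer
masks make pooled counts exact. The moments vector is padded with
mask-only entries so its length is uninformative.

## Obfuscated covariate projection

Nodes encode their slices two-sidedly with seed-derived matrices
$O$ having *exactly* orthonormal columns (QR of a seeded Gaussian, padded
by a seed-drawn count). Exact orthonormality is a strict instance of the
in-expectation condition the encoding needs, and it turns every decode into
an identity instead of an unbiased estimate — which is what near-perfect
agreement with the plaintext engine requires. All payloads are real-valued;
the conjugate transpose reduces to the transpose.

One *global* $O_Z \in \mathbb{R}^{(N+k_Z)\times N}$ is shared, and node $p$
uses the column slice for its sample range; this is the only reading under
which the server-side sum of per-node covariate payloads equals the pooled
encoded covariate matrix. For the same reason the phenotype decoy matrix
$M_y$ (with a per-node row slice) and its column permutation $\rho$ are
global. The server computes the encoded projection using the Moore–Penrose
pseudo-inverse of $T = O_Z Z_1 O_{Z'}^\top$: with padded columns $T^\top T$
is structurally rank $C_1$ and literally singular, and the pseudo-inverse is
exactly the object that reproduces the plaintext projector through the
orthonormal factors. A genuine rank deficit ($\mathrm{rank}(T) < C_1$,
collinear covariates) aborts the protocol. The two post-projection scaling
matrices that appear in the encoded-projection expression are redundant
once decode is defined to reproduce the plaintext target exactly; the
package implements that reading and tests against the plaintext projector.

A seeded *linear checksum* column (phenotype plus a known decoy column)
rides along the padded phenotype; because it is a linear identity it
survives the server's projection, and a decode attempted with the wrong
permutation fails loudly.

## Level 0 by consensus ADMM

For each fold and block, the pooled ridge problem
$\min_\beta \sum_p \lVert X_p\beta - y_p\rVert^2 + \lambda\lVert\beta\rVert^2$
is solved by consensus ADMM with exact local solves. Nodes send, once:

* $\mathcal{R}^{(p,k,b)} = Q_b\,(X^\top X + \ell I)^{-1} Q_b^\top$ — the
  local solve operator on the training folds, conjugated into the
  obfuscated coordinates;
* $\mathcal{X}^{(p,k,b)} = k_{\tilde y}^{-1} O^{(k)}_{\tilde y} X^{b}_{(p,k)}
  Q_b^\top$ — the fold-$k$ design payload;
* $\mathcal{Y}^{(p,k)} = k_{\tilde y}^{2}\, O^{(k)}_{\tilde y}\,
  \tilde y_{(p,k)}$ — the fold-$k$ phenotype payload,

after which the server iterates alone for every $\lambda_r$ (one scalar in
its consensus update), with a single learning rate $\ell$ for the whole
grid. Three index reductions are forced by the algebra rather than chosen
freely: $O_{\tilde y}$ can depend only on the fold (cross-penalty Gram
products at Level 1 must decode), $Q$ only on the block (cross-fold payload
products in the ADMM right-hand side must conform), and the scalar
$k_{\tilde y}$ is global. The $k_{\tilde y}^{2}$ factor on the phenotype
payload makes the consensus iterate $k_{\tilde y}$-scaled and the final
server-side prediction payloads *unit*-scale, so the Level-1 system is
literally the plaintext one and the common scale of the residual payloads
cancels in the $\chi^2$ ratio. Because all iterates stay in the column
space of the orthonormal $Q_b$, the encoded recursion is the plaintext
recursion conjugated — the decoded solution solves the pooled ridge
objective exactly at convergence.

Numerical defaults (solver engineering, validated against closed-form
solves): over-relaxation 1.8; penalty $\ell = N_{\mathrm{train}}/(2P)$,
about half the per-node training Gram diagonal for standardized genotypes,
which minimized iteration counts across the penalty grid in our
experiments; early stop when relative primal and dual residuals drop below
$10^{-12}$ (cap 1500). The whole penalty grid shares one iteration loop
(one matrix–matrix product per node per iteration). Non-convergence is
reported with both residuals.

## Level 1 by conjugate gradients, and the association test

The server holds encoded out-of-fold prediction vectors whose pairwise
inner products equal the plaintext ones (left-obfuscations are
norm-preserving), so it assembles $W_{k-1}^\top W_{k-1}$ and solves each
$(W^\top W + \omega_r I)\eta = W^\top \tilde y$ system by conjugate
gradients (exact in at most $BR$ steps; residual tolerance $10^{-12}$, cap
$\min(BR, 200)$). Grid selection by summed encoded out-of-fold RSS is
valid for the same norm-preservation reason. For the association stage
nodes send per-fold encoded test-SNP matrices; the server evaluates the
$\chi^2$ ratio and returns it — it sees the final statistics (optionally
over a seed-shuffled SNP order that nodes undo) but never genotypes,
phenotypes, or true block sizes.

## What the transcript audit checks

The privacy claims are asserted mechanically rather than proved: every
server-visible message kind must belong to a closed catalogue; no payload
dimension of an encoded message may equal an unpadded private dimension (a
node's sample count, the covariate count, a block size) — nodes, who know
all private dimensions, bump seed-drawn pads deterministically to rule out
chance collisions; and no row of any server-visible payload may hash to a
row of any node's raw data. Count tables are exempt from the dimension
check: their $M \times 4$ shape is fixed by the four genotype classes and
carries no private dimension. A degenerate identity-encoding mode (pads 0,
$O = I$) exists so reduction tests can equate the protocol with the
plaintext algebra; `run_ppgwas()` refuses it unless explicitly unlocked.

# The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes and
nothing more:

* **Population structure** — per SNP, an ancestral frequency
  $p \sim U(0.05, 0.95)$ and Balding–Nichols subpopulation frequencies
  $p_s \sim \mathrm{Beta}\!\left(p\tfrac{1-F}{F},
  (1-p)\tfrac{1-F}{F}\right)$ with $F = 0.1$ by default; dosages are
  $\mathrm{Binomial}(2, p_s)$.
* **Family relatedness** — a fraction (default 0.25) of samples form pairs
  sharing one parental haplotype draw (dosage correlation $\approx 0.5$
  within pairs). The generative mechanism behind the published
  "relatedness" knob is not specified anywhere we could follow, so this
  haplotype-duplication scheme is an explicit stand-in.
* **Phenotype** — $y = Z\alpha + X\beta + e$ with $\beta \sim N(0,1)$ on a
  seeded causal set, rescaled so the in-sample variance ratio
  $\mathrm{Var}(X\beta)/\mathrm{Var}(y)$ hits the target heritability
  exactly; Gaussian noise takes up the remainder (an error is raised if the
  covariate variance leaves no room).
* **Missingness** — uniform at rate 0.02 by default, so QC filters are
  exercised; default two subpopulations.

Not emulated: linkage disequilibrium between SNPs (draws are independent
across SNPs), imputation uncertainty, binary traits, X-chromosome dosage
conventions, platform batch structure. Passing tests therefore certify the
*algebraic* equivalence of the distributed and centralized engines and the
statistical calibration of the test under this generative model — not
robustness to LD structure or real-data artefacts.

# Design choices that were genuinely open

* **Fold assignment** is a seeded *global* interleave (shuffle all $N$
  global indices once, deal folds cyclically) rather than a per-node
  interleave. Either satisfies "every node has data in every fold" at
  realistic sizes (violations raise an error), but only a
  partition-independent rule makes results provably invariant to how the
  same pooled study is split across nodes — an invariance the test suite
  asserts at $10^{-8}$.
* **Pad magnitudes** are seed-drawn from $\{8,\dots,64\}$ (smaller ranges
  for the low-dimensional phenotype payloads). Nothing pins them; they only
  need to hide true sizes, and this range keeps the extra flops negligible.
* **The non-zero payload constant** $k_{\tilde y}$ is drawn from
  $\pm[0.5, 2]$: "non-zero" is the only requirement, and bounding it away
  from zero and infinity preserves conditioning.
* **Level-1 selection** uses the cross-validated per-fold criterion
  (summed out-of-fold RSS) throughout; the non-CV single-fit selection is
  its degenerate special case and is not used.
* **p-values server-side or node-side**: both ends can compute them from
  $\chi^2$; the package computes them server-side by default and nodes
  recompute them after unshuffling, which costs nothing and keeps the two
  backends' outputs identical.
* **Archive layout**: genotypes are stored blockwise in a self-defined,
  versioned single-file archive (magic header, JSON manifest, per-block
  gzip segments, dense or sparse block encoding). The published format's
  internal key layout is not documented, so no compatibility is claimed.

# Problem sizes used by the checks

The equivalence and audit checks run on a simulated study of $N = 2000$
samples, $M = 5000$ SNPs, $C = 3$ covariates, 3 nodes, $K = R = 5$,
Level-0 blocks of 500 SNPs, heritability 0.5 with 50 causal SNPs — the
package's scaled-down standing twin of a full GWAS. Component oracles
(ADMM vs closed form, CG vs dense solves) use 20 seeded instances with
$N \le 200$; node-count invariance uses $N = 600$, $M = 600$ across
$P \in \{1, 2, 4\}$; null calibration uses $N = 1000$, $M = 2000$ with
heritability 0. At these sizes the full suite runs on one CPU in minutes.

# Known limitations

* Semi-honest, non-colluding adversaries only: no malicious-party
  hardening, no differential-privacy noise, no leakage quantification
  beyond the mechanical transcript audit; the seeded RNG streams are not
  cryptographic-strength and seed agreement itself is assumed done.
* Quantitative traits only; no binary-trait (logistic) testing.
* No LD pruning, sample-level QC, or cross-site harmonization of variant
  identity; SNP panels must already agree across nodes.
* ADMM is an iterative solver: results match the closed form to solver
  tolerance, not to machine epsilon; the defaults leave $\chi^2$ agreement
  around $10^{-8}$ relative at the standing study scale and can be
  tightened (at iteration cost) via `admm_tol`.
* Fault tolerance is limited to clean aborts: a node dropping mid-protocol
  ends the session with a stage label, with no restart.
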