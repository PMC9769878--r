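# kepmine

Mining and maturation modelling of KEX2-processed repeat proteins (KEPs)
in fungal proteomes.

Many fungi secrete short peptides that are born as parts of a larger
precursor protein: an N-terminal signal peptide followed by tandem
repeats of a core peptide, each repeat flanked by a dibasic motif (KR,
RR, KK or RK). In the late Golgi the kexin endoproteinase KEX2 cleaves
on the C-terminal side of these dibasic motifs; the carboxypeptidase
KEX1 then removes the C-terminal basic residues, and in many precursors
the dipeptidyl aminopeptidase STE13 trims N-terminal X-P / X-A
dipeptides (X often D/E), as known from the ascomycete alpha-pheromone
pathway. Peptides starting with glutamine frequently cyclize to
pyroglutamate (loss of NH3, -17.026549 Da). `kepmine` is for
researchers who want to find such precursors in a predicted proteome
and to connect them to peptidomics data: it calls KEPs from a FASTA
proteome, predicts the mature peptides with their monoisotopic masses,
and matches observed neutral masses at ppm tolerance.

## The screen

A precursor with sequence $s$ is cleaved in silico after every dibasic
motif occurrence; overlapping motifs each cut. The resulting fragments
$f_1, \dots, f_n$ are compared all-against-all with a Smith–Waterman
local alignment (BLOSUM62, gap open 11 / extend 1) and

$$\mathrm{PID}(f_i, f_j) = 100 \cdot
\frac{\text{identical aligned positions}}{\text{alignment length incl. gaps}}$$

Two fragments are *similar* if either tier holds:

| tier | length gates | identity |
|------|--------------|----------|
| 1 | $\lvert\,|f_i|-|f_j|\,\rvert < 30$ | $\mathrm{PID} \ge 70\%$ |
| 2 | $|f_i| < 20$, $|f_j| < 20$, $\lvert\,|f_i|-|f_j|\,\rvert < 8$ | $\mathrm{PID} \ge 40\%$ |

A protein is called a KEP when it has a signal peptide (annotation from
an external predictor, e.g. SignalP), at least 2 cleavage sites, length
at most 800 residues, and at least one fragment similar to at least 2
other fragments. Alignments spanning less than half of the shorter
fragment are treated as no match (see the vignette for why).

The maturation model composes, per fragment: KEX1 trim variants (0–2
C-terminal K/R) → STE13 trim variants → optional C-terminal truncation →
pyroglutamate variants, with a 2–60 residue length window, and computes
neutral monoisotopic masses (residue masses + 18.010565 Da water +
modification deltas). Matching reports every observed/predicted pair
with $|\mathrm{ppm}| \le$ tolerance, where
$\mathrm{ppm} = 10^6\,(m_\mathrm{obs}-m_\mathrm{theo})/m_\mathrm{theo}$
(default tolerance 10 ppm, inclusive).

## Worked example

```r
library(kepmine)

## 1. mine a synthetic proteome with known ground truth
fix   <- simulateProteome(seed = 42, nKeps = 10, nDecoysPerClass = 8)
calls <- mineProteome(fix$precursors)
calls
#> KepCallSet: 50 precursors screened, 10 accepted as KEPs
#>   rejections: no_repeat=8, no_signal=8, too_few_sites=16, too_long=8

## 2. predict mature peptides of a two-core precursor
ps <- PrecursorSet(
    c(kep490115 = paste0("M", strrep("L", 18),
                         "EADAQMRPPSWKR", "EAQYKAPSWRR", "EAQYKAPSWRR")),
    hasSignal = TRUE, signalCleavagePos = 19L)
pep <- enumerateMaturePeptides(ps)
subset(as.data.frame(pep), sequence %in% c("QMRPPSW", "QYKAPSW"))
#>    precursor_id start end sequence modifications ... monoisotopic_mass
#> 7     kep490115    24  30  QMRPPSW                          900.4276
#> 8     kep490115    24  30  QMRPPSW       pyroGlu            883.4011
#> 16    kep490115    35  41  QYKAPSW                          878.4287
#> 17    kep490115    35  41  QYKAPSW       pyroGlu            861.4021
```

KEX2 releases `EADAQMRPPSWKR`; KEX1 removes `KR`; STE13 peels `EA` and
`DA`; the remaining `QMRPPSW` is also emitted as its pyro-Q form 17.03 Da
lighter. `QYKAPSW` comes from both identical downstream repeats
(`multiplicity` 2). Matching two observed neutral masses:

```r
matchMasses(c(900.427607, 861.402104), pep, ppmTol = 10)
#>   sample_id observed_mass sequence modifications theoretical_mass  ppm_error
#> 1      obs1      900.4276  QMRPPSW                       900.4276 -0.0002
#> 2      obs2      861.4021  QYKAPSW       pyroGlu         861.4021  0.0004
```

A command-line wrapper with `mine`, `mature`, `match` and `simulate`
subcommands is installed at
`system.file("scripts", "kepmine.R", package = "kepmine")`.

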