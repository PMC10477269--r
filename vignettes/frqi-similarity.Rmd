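---
title: "Quantum strip-qubit similarity for nucleotide sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum strip-qubit similarity for nucleotide sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frqiseq)
```

## The model

`frqiseq` scores the similarity of two equal-length nucleotide sequences by
encoding each as an angle-parameterized quantum state and interfering the two
encodings on an auxiliary *strip* qubit.

Each residue is assigned a state-representation angle $\theta$:

| residue | $\theta$ (rad) |
|---------|-----------|
| A | $\pi$ |
| C | $\pi/2$ |
| T | $\pi/6$ |
| G | $0$ |

Under the flexible representation of quantum images (FRQI), a sequence of
length $2^k$ is stored on $k$ *index* qubits in uniform superposition plus one
*value* qubit, whose state at position $i$ is
$\cos(\theta_i/2)\,|0\rangle + \sin(\theta_i/2)\,|1\rangle$. Note the
half-angle: the tabulated $\theta$ is the state-representation angle, and the
value-qubit amplitudes use $\alpha_i = \theta_i/2$. This convention is what
makes the uniform-pair probabilities below come out right (e.g. A vs C gives
$\tfrac12(1-\cos(\pi/4)) \approx 0.146$); SDK-specific gate parameterizations
that divide the angle further are bookkeeping details of particular toolkits
and are not part of this package's contract.

The comparison circuit is a Hadamard-test construction:

1. Hadamards put the strip qubit and all index qubits into uniform
   superposition.
2. For each position $i$ and each strip value $s \in \{0,1\}$, a
   multi-controlled RY writes the reference angle ($s=0$) or the compared
   angle ($s=1$) onto the value qubit.
3. A final Hadamard on the strip interferes the two branches, and the strip
   is measured.

The probability of reading 1 on the strip is

$$P_1 = \frac{1}{2}\left(1 - \frac{1}{2^k}\sum_i
\cos(\alpha_i - \beta_i)\right),$$

where $\alpha$, $\beta$ are the FRQI half-angles of the two sequences. The
similarity score is $\mathrm{sim} = 1 - 2 P_1$: 1 for identical encodings, 0
when the branches are orthogonal. With all angles in $[0, \pi]$, every
per-position overlap $\cos(\alpha_i - \beta_i)$ is nonnegative, so
$P_1 \le 0.5$ and $\mathrm{sim} \in [0, 1]$; maps with angles outside
$[0, \pi]$ are rejected at construction so the score's range is guaranteed.

For uniform four-position pairs against all-A, the exact values are
$P_1 = 0$ (A), $0.146$ (C), $0.371$ (T) and $0.5$ (G):

```{r table2}
sapply(c("AAAA", "CCCC", "TTTT", "GGGG"), function(s)
  round(seqsim("AAAA", s)$p1, 3))
```

## Three computation methods

* `analytic` (default): evaluates the closed form directly. Exact and O(n).
* `statevector`: builds the gate-level circuit and simulates all $2^{k+2}$
  complex amplitudes. Exact; exists to exercise the quantum construction
  end-to-end and agrees with the closed form to $10^{-9}$ (tested on random
  pairs).
* `shots`: additionally draws $N$ seeded Bernoulli measurement outcomes of
  the strip qubit and estimates $\hat P_1$ as the fraction of 1s. The default
  `shots = 8000` mirrors the original experiment's repetition count. The
  estimator is the plain frequency, with no bias correction, and its error
  shrinks as $O(1/\sqrt{N})$.

```{r methods}
seqsim("AAAA", "TTTT", method = "statevector")$p1
seqsim("AAAA", "TTTT", method = "shots", shots = 8000, seed = 7)$p1
```

A seed is mandatory in `shots` mode — there is no silently nondeterministic
run. Sampling uses a locally seeded generator and restores the caller's RNG
state. Because the circuit has a single terminal measurement, per-shot state
collapse is unnecessary: the marginal $P_1$ is read analytically from the
statevector and the shot histogram is one binomial draw, which is
distributionally exact and fast.

## Padding and mixed lengths

The index register needs $2^k$ basis states, so sequences are right-padded
with the map's pad symbol (G, angle 0) to the next power of two, and both
members of a pair are padded to the same register size. Padded positions
match on both sides by construction and inflate the raw score;
`similarity_corrected()` removes their guaranteed contribution:
$(N(1-2P_1) - n_\text{pad})/n_\text{real}$ with $N$ the padded length.

Mixed-length input has no canonical treatment in this construction; our
choice (opt-in via `pad = TRUE`, or `--pad` on the command line) is to
right-pad the shorter sequence with the pad symbol up to the longer length.
Those fill positions face real residues of the longer sequence, so they are
counted as compared positions, not as correctable padding — a fill G against
a real A is a genuine mismatch. Gaps and alignment are out of scope: the
method is strictly positional.

Ambiguity codes (N, R, Y, ...) are rejected rather than guessed; input is
uppercased before lookup. Users may supply other alphabets (e.g. amino
acids) as a plain-text `symbol<TAB>radians` file via `read_angle_map()`,
subject to the $[0, \pi]$ constraint.

## Circuit-level choices

* **Qubit layout**: `[strip, index_(k-1) .. index_0, value]`, position index
  big-endian on the index register, statevector little-endian (basis index
  bit $q$ = qubit $q$). The layout is a free convention; $P_1$ is invariant
  to it.
* **Multi-controlled RY decomposition**: controls on 0 are X-conjugated, and
  the all-ones-controlled rotation is expanded with the Gray-code
  uniformly-controlled rotation ladder ($2^c$ RY + $2^c$ CX, no ancillas).
  The ancilla-free choice reflects the tight qubit budget of small hardware;
  unitary equivalence is verified against a dense-matrix oracle to
  $10^{-9}$.
* **Zero-angle rotations** (G positions) are emitted by default, keeping the
  construction uniform across positions; `drop_zero_angles = TRUE` elides
  them.
* **Depth** is the as-soon-as-possible layering of the emitted gate list
  (each gate at one plus the maximum layer of its qubits), measurement
  excluded, no commutation or cancellation. Under this rule the canonical
  15-gate Toffoli decomposition (9 single-qubit gates, 6 CNOTs) has depth 11.
* **OpenQASM 2.0 export** emits `u3`/`cx`/`h`/`t`/`tdg`/`ry`/`measure`
  statements with 17-significant-digit angles, decomposing composite gates
  first, so an independent parser recovers the same unitary.

## What the simulator does and does not model

The statevector backend is an idealized, noiseless executor: it tracks all
amplitudes exactly and models only binomial sampling noise in `shots` mode.
Hardware effects — decoherence, gate error, readout error — are not modelled.
The original experiment's hardware-measured estimate for the all-A vs all-T
pair (0.378 at 8000 shots) sits within the $3\sigma$ binomial band
($\pm 0.016$) of the ideal 0.3706, so sampling noise alone accounts for a
deviation of that size, but a noisy device could fall outside it.

The fixture generator (`generate_fixture()`) emulates point substitutions
only: a uniform random sequence with a chosen number of positions mutated to
a different symbol, plus the closed-form expected $P_1$. It does not emulate
indels, homopolymer error profiles, or base-composition bias of real reads,
so passing tests demonstrate correctness of the encoding/circuit/estimator
chain, not robustness to real sequencing artifacts.

## Numerical notes and limitations

* Probabilities are clipped to $[0,1]$ and the corrected score to $[-1,1]$
  against floating-point drift; `similarity_score()` rejects $P_1 > 0.5$
  beyond a $10^{-9}$ tolerance since it is unreachable under valid maps.
* Statevector simulation is capped at 20 qubits (16 Mi amplitudes) by
  default; the comparison circuit uses $k+2$ qubits for sequence length
  $2^k$, so the cap corresponds to sequences of length $2^{18}$. The
  analytic method has no such limit and is the default.
* Problem sizes in the test suite are chosen to keep the dense-matrix
  oracle tractable: unitary equivalence checks run on at most 5 qubits,
  property suites use 100 random pairs of length up to 16, and shot
  concentration uses 1000 seeds at 8000 shots.
* The score is a global phase-angle overlap, not an alignment: it has no
  notion of gaps, and two sequences differing by a single shift score as
  largely dissimilar. Interpret it position-wise.
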