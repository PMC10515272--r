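# Shipped SSP family motif rules. Editable: motif syntax uses amino-acid
# letters, `x` for any residue and `[..]` for alternatives. `search_region`
# is one of mature / full / c_terminal_k (last `c_terminal_k` residues of
# the mature sequence). `n_cys` constrains the exact cysteine count of the
# mature sequence. Lower `priority` wins; PTM motifs rank before generic
# cysteine-based rules so each peptide is counted once.
#
# Only families with published motif evidence carry default motifs:
#   CEP  - conserved SPGxG[H/N] box of the CEP domain
#   CLE  - conservative CLE dodecapeptide box near the C terminus
#   PNP  - K(V/I)(V/I)D and LSxxA(F/I)xxIA boxes co-occurring
#   RALF - four conserved mature cysteines plus the RR dibasic site
rules:
  - family: CEP
    motif: SPGxG[HN]
    search_region: mature
    priority: 1
  - family: CLE
    motif: RxxPxGPDPxHH
    search_region: c_terminal_k
    c_terminal_k: 30
    priority: 2
  - family: PNP
    motif: K[VI][VI]D
    motif2: LSxxA[FI]xxIA
    search_region: mature
    priority: 3
  - family: RALF
    motif: RR
    n_cys: 4
    search_region: mature
    priority: 4
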