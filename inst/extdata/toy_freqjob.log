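 Entering harmonic frequency analysis (toy three-atom system)
 Harmonic frequencies (cm**-1), Raman scattering activities (A**4/AMU)
                      1                      2                      3
 Frequencies --   1000.0000   2000.0000   3000.0000
 Red. masses --      1.0000      1.0000      1.0000
 Raman Activ --      1.0000      2.0000      3.0000
  Atom  AN      X      Y      Z      X      Y      Z      X      Y      Z
     1   6    0.10   0.00   0.00   0.00   0.10   0.00   0.00   0.00   0.10
     2   1    0.00   0.20   0.00   0.20   0.00   0.00   0.00   0.20   0.00
     3   1    0.00   0.00   0.30   0.00   0.00   0.30   0.30   0.00   0.00
 Normal termination.
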