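# Mass-action model of the yeast GAL regulatory switch (nine state species).
# State ordering: G3, Gint, G3a, G4, G80, G480, G803a, G2, G1
#   G3    Gal3p protein            G480  Gal4p:Gal80p complex
#   Gint  internalized galactose   G803a Gal80p:Gal3p* active complex
#   G3a   active Gal3p protein     G2    Gal2p protein (permease)
#   G4    Gal4p protein            G1    Gal1p protein (reporter)
#   G80   Gal80p protein
# External galactose Gex is a constant input (1 mM = 1000 uM).
species:
  - G3
  - Gint
  - G3a
  - G4
  - G80
  - G480
  - G803a
  - G2
  - G1
constants:
  Gex: 1000.0
parameters:
  k1: 0.1814
  k2: 8.4586e-4
  kr2: 16.6691
  mu3: 1.0
  k4: 3.0749
  kr4: 0.1317
  k5: 22.0604
  mu6: 1.0
  k7: 29.6549
  k8: 181.4157
  k9: 1.0
  k10: 1.0
  k11: 85.8185
  kr11: 4.7482e-2
  mu12: 1.0
  mu13: 1.0
  mu14: 1.0
  mu15: 1.0
  mu16: 1.0
  mu17: 1.0
  mu18: 1.0
  k19: 36.6342
  kr19: 222.0536
reactions:
  - Gex + G2 -> Gex + G2 + Gint @ k1     # galactose import, Gal2p-mediated
  - G3 + Gint -> G3a @ k2                # Gal3p activation by galactose
  - G3a -> G3 + Gint @ kr2               # reverse of activation
  - G3a -> 0 @ mu3                       # degradation of active Gal3p
  - G480 + G3a -> G803a + G4 @ k4        # Gal3p* strips Gal80p off Gal4p
  - G803a + G4 -> G480 + G3a @ kr4       # reverse exchange
  - 0 -> G4 @ k5                         # basal Gal4p expression
  - G4 -> 0 @ mu6                        # Gal4p degradation
  - G4 -> G4 + G80 @ k7                  # Gal4p-activated GAL80 expression
  - G4 -> G4 + G3 @ k8                   # Gal4p-activated GAL3 expression
  - G4 -> G4 + G2 @ k9                   # Gal4p-activated GAL2 expression
  - G4 -> G4 + G1 @ k10                  # Gal4p-activated GAL1 expression
  - G4 + G80 -> G480 @ k11               # Gal80p inhibition of Gal4p
  - G480 -> G4 + G80 @ kr11              # complex dissociation
  - G480 -> 0 @ mu12                     # complex degradation
  - G3 -> 0 @ mu13                       # Gal3p degradation
  - G80 -> 0 @ mu14                      # Gal80p degradation
  - G803a -> 0 @ mu15                    # Gal80p:Gal3p* degradation
  - Gint -> 0 @ mu16                     # internal galactose consumption
  - G2 -> 0 @ mu17                       # Gal2p degradation
  - G1 -> 0 @ mu18                       # Gal1p degradation
  - G803a -> G80 + G3a @ k19             # Gal80p:Gal3p* dissociation
  - G80 + G3a -> G803a @ kr19            # Gal80p sequestration by Gal3p*
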