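A:
  description: Antipsychotics specifically for SZ
  groups: [SZ]
B:
  description: Neurotransmitter receptor-site binders used in BD and SZ
  groups: [BD, SZ]
C:
  description: Sedatives, hypnotics, anticonvulsants and analgesics in BD and SZ
  groups: [BD, SZ]
D:
  description: Mood stabilizers specifically for BD
  groups: [BD]
E:
  description: Psycho-stimulants used in BD
  groups: [BD]
F:
  description: Serotonin and adrenergic antagonists for BD
  groups: [BD]
G:
  description: Serotonin antagonist for SZ
  groups: [SZ]
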