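# Example visual style map: shapes and colors for the 677-node
# demonstration fixture, keyed by functional subsystem. Module entries win
# over class entries, which win over the default.
module:
  virulence_factor_synthesis: {shape: square, fill: "#d62728"}
  central_metabolism: {shape: round-rectangle, fill: "#555555"}
  sulfur_metabolism: {shape: round-rectangle, fill: "#9edae5"}
  lipid_synthesis: {shape: rectangle, fill: "#2ca02c"}
  ethanol_pyruvate_metabolism: {shape: rectangle, fill: "#1f3a93"}
  cell_wall_lps_synthesis: {shape: diamond, fill: "#d62728"}
  trna_synthetases: {shape: diamond, fill: "#1f3a93"}
  unassigned: {shape: circle, fill: "#ffdd57"}
class:
  metabolite: {shape: ellipse, fill: "#2a4d9b"}
  reaction: {shape: circle, fill: "#ffdd57"}
default: {shape: circle, fill: "#b8b8b8"}
edge: {color: "#999999", width: 1}
cell: 24
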