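# Dynastic mass-unit conversion table.
# grams_per_fen gives the metric value of one Fen in each dynastic system;
# fen_per_unit gives the fixed unit chain 1 Liang = 10 Qian = 100 Fen.
# Users may point standardize_dosage()/convert_to_grams() at an extended
# copy of this file to support further units or dynasties.
version: 1
grams_per_fen:
  SongYuan: 0.4
  MingQing: 0.37
fen_per_unit:
  Fen: 1
  Qian: 10
  Liang: 100
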