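PC:
  backbone: C8H16NO8P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M+Cl]-'
  extra_adducts:
  - '[M+H]+'
  - '[M+Na]+'
  membrane: yes
  lyso_partner: LPC
  grid:
    c_range:
    - 30.0
    - 40.0
    c_by: 2.0
    db_range:
    - 0.0
    - 6.0
    oh: []
PC-O:
  backbone: C8H18NO7P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M+Cl]-'
  extra_adducts:
  - '[M+H]+'
  - '[M+Na]+'
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 38.0
    c_by: 2.0
    db_range:
    - 0.0
    - 5.0
    oh: []
PE:
  backbone: C5H10NO8P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: LPE
  grid:
    c_range:
    - 32.0
    - 40.0
    c_by: 2.0
    db_range:
    - 0.0
    - 6.0
    oh: []
PE-P:
  backbone: C5H10NO7P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 40.0
    c_by: 2.0
    db_range:
    - 1.0
    - 6.0
    oh: []
PI:
  backbone: C9H15O13P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: LPI
  grid:
    c_range:
    - 32.0
    - 40.0
    c_by: 2.0
    db_range:
    - 0.0
    - 6.0
    oh: []
PS:
  backbone: C6H10NO10P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: LPS
  grid:
    c_range:
    - 32.0
    - 40.0
    c_by: 2.0
    db_range:
    - 0.0
    - 6.0
    oh: []
PA:
  backbone: C3H5O8P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 40.0
    c_by: 2.0
    db_range:
    - 0.0
    - 6.0
    oh: []
PG/BMP:
  backbone: C6H11O10P
  chains: 2
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: LPG
  grid:
    c_range:
    - 32.0
    - 44.0
    c_by: 2.0
    db_range:
    - 0.0
    - 12.0
    oh: []
CL:
  backbone: C9H14O17P2
  chains: 4
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-2H]2-'
  extra_adducts: []
  membrane: yes
  lyso_partner: LCL
  grid:
    c_range:
    - 68.0
    - 76.0
    c_by: 2.0
    db_range:
    - 4.0
    - 10.0
    oh: []
LPC:
  backbone: C8H18NO7P
  chains: 1
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M+Cl]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 16.0
    - 22.0
    c_by: 2.0
    db_range:
    - 0.0
    - 4.0
    oh: []
LPE:
  backbone: C5H12NO7P
  chains: 1
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 16.0
    - 22.0
    c_by: 2.0
    db_range:
    - 0.0
    - 4.0
    oh: []
LPI:
  backbone: C9H17O12P
  chains: 1
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 16.0
    - 22.0
    c_by: 2.0
    db_range:
    - 0.0
    - 4.0
    oh: []
LPS:
  backbone: C6H12NO9P
  chains: 1
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 16.0
    - 22.0
    c_by: 2.0
    db_range:
    - 0.0
    - 4.0
    oh: []
LPG:
  backbone: C6H13O9P
  chains: 1
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 16.0
    - 22.0
    c_by: 2.0
    db_range:
    - 0.0
    - 4.0
    oh: []
LCL:
  backbone: C9H16O16P2
  chains: 3
  sphingoid: no
  quant_polarity: negative
  quant_adduct: '[M-2H]2-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 54.0
    - 60.0
    c_by: 2.0
    db_range:
    - 2.0
    - 6.0
    oh: []
Cer:
  backbone: HNO
  chains: 2
  sphingoid: yes
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 42.0
    c_by: 2.0
    db_range:
    - 1.0
    - 2.0
    oh:
    - 2
HexCer:
  backbone: C6H11NO6
  chains: 2
  sphingoid: yes
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 42.0
    c_by: 2.0
    db_range:
    - 1.0
    - 2.0
    oh:
    - 2
GM3:
  backbone: C23H38N2O19
  chains: 2
  sphingoid: yes
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 42.0
    c_by: 2.0
    db_range:
    - 1.0
    - 2.0
    oh:
    - 2
Sulf:
  backbone: C6H11NO9S
  chains: 2
  sphingoid: yes
  quant_polarity: negative
  quant_adduct: '[M-H]-'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 42.0
    c_by: 2.0
    db_range:
    - 1.0
    - 2.0
    oh:
    - 2
SM:
  backbone: C5H13N2O4P
  chains: 2
  sphingoid: yes
  quant_polarity: positive
  quant_adduct: '[M+H]+'
  extra_adducts: []
  membrane: yes
  lyso_partner: ~
  grid:
    c_range:
    - 32.0
    - 42.0
    c_by: 2.0
    db_range:
    - 1.0
    - 2.0
    oh:
    - 2
DG:
  backbone: C3H4O5
  chains: 2
  sphingoid: no
  quant_polarity: positive
  quant_adduct: '[M+NH4]+'
  extra_adducts: []
  membrane: no
  lyso_partner: ~
  grid:
    c_range:
    - 30.0
    - 38.0
    c_by: 2.0
    db_range:
    - 0.0
    - 4.0
    oh: []
TG:
  backbone: C3H2O6
  chains: 3
  sphingoid: no
  quant_polarity: positive
  quant_adduct: '[M+NH4]+'
  extra_adducts: []
  membrane: no
  lyso_partner: ~
  grid:
    c_range:
    - 48.0
    - 56.0
    c_by: 2.0
    db_range:
    - 0.0
    - 6.0
    oh: []
CE:
  backbone: C27H44O2
  chains: 1
  sphingoid: no
  quant_polarity: positive
  quant_adduct: '[M+NH4]+'
  extra_adducts: []
  membrane: no
  lyso_partner: ~
  grid:
    c_range:
    - 14.0
    - 20.0
    c_by: 2.0
    db_range:
    - 0.0
    - 2.0
    oh: []
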