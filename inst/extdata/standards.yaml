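PC:
  species: PC(28:0)
  pmol: 10.0
PC-O:
  species: PC-O(28:0)
  pmol: 10.0
PE:
  species: PE(28:0)
  pmol: 10.0
PE-P:
  species: PE-P(28:1)
  pmol: 10.0
PI:
  species: PI(28:0)
  pmol: 10.0
PS:
  species: PS(28:0)
  pmol: 10.0
PA:
  species: PA(28:0)
  pmol: 10.0
PG/BMP:
  species: PG/BMP(28:0)
  pmol: 10.0
CL:
  species: CL(56:0)
  pmol: 10.0
LPC:
  species: LPC(14:0)
  pmol: 10.0
LPE:
  species: LPE(14:0)
  pmol: 10.0
LPI:
  species: LPI(14:0)
  pmol: 10.0
LPS:
  species: LPS(14:0)
  pmol: 10.0
LPG:
  species: LPG(14:0)
  pmol: 10.0
LCL:
  species: LCL(42:0)
  pmol: 10.0
Cer:
  species: Cer(30:1:2)
  pmol: 10.0
HexCer:
  species: HexCer(30:1:2)
  pmol: 10.0
GM3:
  species: GM3(30:1:2)
  pmol: 10.0
Sulf:
  species: Sulf(30:1:2)
  pmol: 10.0
SM:
  species: SM(30:1:2)
  pmol: 10.0
DG:
  species: DG(24:0)
  pmol: 10.0
TG:
  species: TG(39:0)
  pmol: 10.0
CE:
  species: CE(12:0)
  pmol: 10.0
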