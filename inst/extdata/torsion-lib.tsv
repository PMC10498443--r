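# Built-in torsion library.
# Format: SMARTS<TAB>angle:tolerance[,angle:tolerance...]
# Patterns describe a linear path of three or four atoms; for four-atom
# paths the rotor is the bond between atoms 2 and 3, for three-atom paths
# the bond between atoms 1 and 2. First matching entry wins; user
# libraries are searched before this one. Angles in degrees.
[OX1]=[CX3][NX3][!#1]	180:20,0:20
[OX1]=[CX3][OX2][#6]	180:20,0:20
[OX1]=[CX3][SX2][#6]	180:20,0:20
[c][c]!@[c][c]	45:15,135:15,225:15,315:15
[c][c]!@[NX3][!#1]	30:20,150:20,210:20,330:20
[CX3]=[CX3]!@[CX3]=[CX3]	180:20,0:20
[CX3]=[CX3]!@[CX3]=[OX1]	180:20,0:20
[c][c]!@[CX3]=[OX1]	0:20,180:20
[#6][CX4]!@[OX2][#6]	60:20,180:20,300:20
[#6][CX4]!@[NX3][#6]	60:20,180:20,300:20
[#6][CX4]!@[SX2][#6]	60:20,180:20,300:20
[c][c]!@[CX4][!#1]	90:30,270:30
[CX3](=[OX1])[CX4][!#1]	0:20,120:20,240:20
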