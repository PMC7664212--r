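# Synthetic stand-in FFA standards library (the original in-house web
# library is not published). Reference RIs for unsaturated entries follow
# the heuristic RI = 100*C - 45*(C=C); Cn:0 entries sit at RI = 100*n by
# the ladder convention; hydroxy/oxo/bile-acid RIs are plausible synthetic
# placements. Fixture data for testing and simulation only.
name,formula,reference_ri,class
valeric acid,C5H10O2,500,saturated FA
caproic acid,C6H12O2,600,saturated FA
heptanoic acid,C7H14O2,700,saturated FA
caprylic acid,C8H16O2,800,saturated FA
pelargonic acid,C9H18O2,900,saturated FA
capric acid,C10H20O2,1000,saturated FA
undecanoic acid,C11H22O2,1100,saturated FA
lauric acid,C12H24O2,1200,saturated FA
tridecanoic acid,C13H26O2,1300,saturated FA
myristic acid,C14H28O2,1400,saturated FA
pentadecanoic acid,C15H30O2,1500,saturated FA
palmitic acid,C16H32O2,1600,saturated FA
margaric acid,C17H34O2,1700,saturated FA
stearic acid,C18H36O2,1800,saturated FA
nonadecanoic acid,C19H38O2,1900,saturated FA
arachidic acid,C20H40O2,2000,saturated FA
heneicosanoic acid,C21H42O2,2100,saturated FA
behenic acid,C22H44O2,2200,saturated FA
tricosanoic acid,C23H46O2,2300,saturated FA
lignoceric acid,C24H48O2,2400,saturated FA
myristoleic acid,C14H26O2,1355,monounsaturated FA
pentadecenoic acid,C15H28O2,1455,monounsaturated FA
palmitoleic acid,C16H30O2,1555,monounsaturated FA
oleic acid,C18H34O2,1755,monounsaturated FA
gondoic acid,C20H38O2,1955,monounsaturated FA
erucic acid,C22H42O2,2155,monounsaturated FA
nervonic acid,C24H46O2,2355,monounsaturated FA
linoleic acid,C18H32O2,1710,polyunsaturated FA
alpha-linolenic acid,C18H30O2,1665,polyunsaturated FA
eicosadienoic acid,C20H36O2,1910,polyunsaturated FA
dihomo-gamma-linolenic acid,C20H34O2,1865,polyunsaturated FA
arachidonic acid,C20H32O2,1820,polyunsaturated FA
eicosapentaenoic acid,C20H30O2,1775,polyunsaturated FA
docosadienoic acid,C22H38O2,2110,polyunsaturated FA
adrenic acid,C22H36O2,2020,polyunsaturated FA
docosapentaenoic acid,C22H34O2,1975,polyunsaturated FA
docosahexaenoic acid,C22H32O2,1930,polyunsaturated FA
cholic acid,C24H40O5,2050,bile acid
chenodeoxycholic acid,C24H40O4,2120,bile acid
deoxycholic acid,C24H40O4,2150,bile acid
lithocholic acid,C24H40O3,2250,bile acid
isobutyric acid,C4H8O2,380,saturated FA
isovaleric acid,C5H10O2,470,saturated FA
2-methylbutyric acid,C5H10O2,480,saturated FA
4-methylvaleric acid,C6H12O2,570,saturated FA
2-methylhexanoic acid,C7H14O2,670,saturated FA
cerotic acid,C26H52O2,2600,saturated FA
4-methyl-2-oxovaleric acid,C6H10O3,540,other
3-methyl-2-oxobutanoic acid,C5H8O3,450,other
levulinic acid,C5H8O3,430,other
2-hydroxybutyric acid,C4H8O3,330,other
3-hydroxybutyric acid,C4H8O3,310,other
2-hydroxyoctanoic acid,C8H16O3,740,other
2-oxooctanoic acid,C8H14O3,720,other
3-hydroxydecanoic acid,C10H20O3,930,other
2-hydroxydodecanoic acid,C12H24O3,1130,other
2-hydroxypalmitic acid,C16H32O3,1520,other
12-hydroxystearic acid,C18H36O3,1700,other
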