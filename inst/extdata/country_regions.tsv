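country	region
US	NORTH AMERICA
CA	NORTH AMERICA
MX	NORTH AMERICA
CU	NORTH AMERICA
DO	NORTH AMERICA
GT	NORTH AMERICA
PA	NORTH AMERICA
CR	NORTH AMERICA
BR	SOUTH AMERICA
AR	SOUTH AMERICA
CL	SOUTH AMERICA
CO	SOUTH AMERICA
PE	SOUTH AMERICA
VE	SOUTH AMERICA
EC	SOUTH AMERICA
UY	SOUTH AMERICA
GB	EUROPE
FR	EUROPE
DE	EUROPE
IT	EUROPE
ES	EUROPE
PT	EUROPE
NL	EUROPE
BE	EUROPE
CH	EUROPE
AT	EUROPE
SE	EUROPE
NO	EUROPE
DK	EUROPE
FI	EUROPE
IE	EUROPE
PL	EUROPE
CZ	EUROPE
SK	EUROPE
HU	EUROPE
RO	EUROPE
BG	EUROPE
GR	EUROPE
HR	EUROPE
SI	EUROPE
RS	EUROPE
UA	EUROPE
RU	EUROPE
EE	EUROPE
LV	EUROPE
LT	EUROPE
LU	EUROPE
IS	EUROPE
MT	EUROPE
CY	EUROPE
JP	ASIA
CN	ASIA
KR	ASIA
IN	ASIA
TW	ASIA
HK	ASIA
SG	ASIA
TH	ASIA
MY	ASIA
ID	ASIA
PH	ASIA
VN	ASIA
IL	ASIA
SA	ASIA
AE	ASIA
TR	ASIA
PK	ASIA
BD	ASIA
LK	ASIA
KZ	ASIA
ZA	AFRICA
EG	AFRICA
NG	AFRICA
KE	AFRICA
MA	AFRICA
TN	AFRICA
DZ	AFRICA
GH	AFRICA
ET	AFRICA
AU	OCEANIA
NZ	OCEANIA
FJ	OCEANIA
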