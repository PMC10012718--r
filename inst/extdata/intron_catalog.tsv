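label	clade_occurrence	family_id	provenance
cox3i507g2	01000000	F01	text
nad9i283g2	01000000	F01	text
atp6i439g2	01110001	F01	inferred
nad4i1399g2	00001110	F01	inferred
nad5i230g2	01011110	F01	inferred
nad7i209g2	01011110	F01	inferred
rps3i74g2	00011111	F01	text
cox2i381g2	00100001	F01	text
nad3i211g2	00100000	F01	inferred
cox3i625g2	10000000	F02	text
nad9i246g2	00100000	F02	text
nad5i392g2	00010000	F02	text
rps10i235g2	00010110	F02	text
nad5i1242g2	00011000	F02	text
rrnLi833g2	10001000	F02	text
nad4i976g2	00111111	F03	text
nad5i1477g2	00111110	F03	text
nad3i140g2	10110001	F03	text
atp9i21g2	01010000	F03	text
sdh3i100g2	01100000	F03	text
cox2i250g2	10000001	F03	text
cox2i97g2	10000000	F04	text
cox2i98g2	00100000	F04	text
nad5i881g2	00100000	F04	text
nad6i444g2	00100000	F04	text
nad9i502g2	00100000	F04	text
atp1i1050g2ii1536g2	00100000	F04	text
cox1i1116g1ii207g2	00100000	F04	text
nad7i676g2	00011110	F04	text
nad4i548g2	10000000	F05	text
nad4Li100g2	10000000	F05	text
nad7i336g2	10000000	F05	text
rpl2i28g2	10000000	F05	text
sdh3i349g2	00010000	F05	text
rps3i249g2	00011100	F06	text
atp1i361g2	00001000	F06	text
cobi783g2	10000000	F06	text
cox1i150g2	00100000	F06	text
atp9i87g2	11110000	F07	text
cobi372g2	10000000	F07	text
nad2i156g2	01011110	F07	text
nad1i477g2	00011110	F07	text
nad7i1113g2	10010000	F08	text
rps14i114g2	10011000	F08	text
atp9i87g2ii1114g2	00010000	F08	text
ccmFCi829g2	11001110	F09	text
rpl2i846g2	00011110	F09	inferred
rps1i25g2	00001000	F09	text
cobi824g2	10000000	F10	text
nad1i669g2	00001111	F10	text
cox1i1149g2	00010000	F10	text
cox1i1149g2ii77g2	00010000	F10	schematic
sdh3i349g2ii104g2	00010000	F10	schematic
atp6i80g2	01110000	F11	text
atp9i95g2	01110000	F11	text
cox1i1064g2	01000000	F11	text
cox1i653g2	00100000	F11	text
nad2i1282g2	00101110	F12	text
cox1i178g2	10000001	F13	text
cox3i171g2	10010000	F13	text
nad1i258g2	00001000	F14	text
cox1i511g2	11010001	F14	text
nad1i287g2	01100000	F15	text
cox2i564g2	00100000	F16	text
nad1i348g2	00100000	F16	text
nad1i728g2	01111110	F17	text
nad4i461g2	01111111	F17	text
cox2i94g2	00010000	F19	text
cox1i323g2	01010000	F19	text
trnS-GCUi43g2	10100001	F24	text
nad5i1455g2	01111110	F25	text
cox2i373g2	01111111	mF26	text
cox2i127g2	10000000	mF27	inferred
atp1i989g2	10000000	mF28	text
atp1i1050g2	10100000	mF28	text
cobi787g2	10000000	mF28	inferred
cox2i691g2	01111110	S	text
cox2i104g2	10010000	S	inferred
nad1i394g2	00000110	S	inferred
nad2i542g2	00000110	S	inferred
nad2i709g2	00001110	S	inferred
nad7i140g2	01001110	S	inferred
nad7i917g2	00001110	S	inferred
cox1i729g2	00000010	S	inferred
cox1i748g2	00001001	S	text
cox1i44g2	10000000	S	inferred
atp1i850g2	10000000	S	inferred
rrnSi839g2	00100000	S	schematic
nad4Li166g2	00100000	S	schematic
cox3i399g2	00100000	S	schematic
atp8i164g2	00100000	S	schematic
nad6i223g2	00100000	S	schematic
nad4i1107g2	00010000	S	schematic
cobi420g2	00010000	S	schematic
atp6i622g2	00010000	S	schematic
rrnLi1462g2	00010000	S	schematic
nad6i530g2	00010000	S	schematic
rrnSi753g2	10000000	S	schematic
nad6i226g2	10000000	S	schematic
cox3i257g2	01000000	S	schematic
nad7i539g2	01000000	S	schematic
atp9i209g2	00000001	F01	text
atp9i214g2	00000001	F01	text
cox3i745g2	00000001	F01	text
cox1i1039g2	00000001	F01	text
cox2i550g2	00000001	F03	text
cox3i34g2	00000001	F03	inferred
cobi274g2	00000001	F12	text
nad1i517g2	00000001	F14	text
cox1i835g2	00000001	F15	text
atp9i145g2	00000001	S	text
cobi399g2	00000001	F17	text
rrnSi1148g2	00000001	F24	text
rrnLi1747g2	00000001	F24	text
nad7i250g2	00000001	F24	text
rrnLi629g2	00000001	F24	text
cobi537g2	00000001	F25	text
cox1i652g2	00000001	S	text
cox1i769g2	00000001	S	inferred
cox1i245g2	00000001	S	inferred
cox1i1147g2	00000001	S	text
nad9i89g2	00000001	S	text
nad2i81g2	00000001	S	text
rrnLi58g2	00000001	F18	schematic
cobi1023g2	00000001	F18	schematic
nad5i622g2	00000001	F18	schematic
rrnSi402g2	00000001	F20	schematic
cox2i314g2	00000001	F20	schematic
nad4i155g2	00000001	F20	schematic
cox3i619g2	00000001	F21	schematic
nad1i996g2	00000001	F21	schematic
rrnLi1205g2	00000001	F21	schematic
atp1i705g2	00000001	F22	schematic
cobi918g2	00000001	F22	schematic
nad3i52g2	00000001	F22	schematic
rrnSi287g2	00000001	F23	schematic
nad4i692g2	00000001	F23	schematic
atp6i170g2	00000001	mF29	schematic
atp9i305g2	00000001	mF29	schematic
cox1i386g2	00000001	S	schematic
cox1i904g2	00000001	S	schematic
cox2i202g2	00000001	S	schematic
cox2i473g2	00000001	S	schematic
cox3i88g2	00000001	S	schematic
cox3i460g2	00000001	S	schematic
cobi143g2	00000001	S	schematic
cobi651g2	00000001	S	schematic
nad1i82g2	00000001	S	schematic
nad1i605g2	00000001	S	schematic
nad2i371g2	00000001	S	schematic
nad3i190g2	00000001	S	schematic
nad4i433g2	00000001	S	schematic
nad4i820g2	00000001	S	schematic
nad5i110g2	00000001	S	schematic
nad5i753g2	00000001	S	schematic
nad5i1637g2	00000001	S	schematic
nad6i105g2	00000001	S	schematic
nad7i462g2	00000001	S	schematic
nad7i836g2	00000001	S	schematic
rrnLi350g2	00000001	S	schematic
rrnSi521g2	00000001	S	schematic
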