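population	location	alt_m	lat_dms	lon_dms	species	chlorotypes
P1	Zhonghoushan, YN	3360	N27°50′11″	E99°41′21″	cyathophorum	H1(5), H2(3)
P2	Wufengshan, YN	3470	N27°48′11″	E99°45′56″	cyathophorum	H2(13)
P3	Xiangcheng, SC	3400	N29°6′17″	E99°38′33″	cyathophorum	H2(8)
P4	Manigange, SC	3910	N31°55′35″	E99°11′59″	cyathophorum	H2(4), H3(3), H4(1)
P5	Xiaosumang, QH	3460	N32°11′10″	E97°14′54″	cyathophorum	H10(10)
P6	Xiaorongga, QH	3400	N32°16′56″	E96°16′4″	cyathophorum	H11(6)
P7	Maozhuang, QH	3520	N32°16′18″	E96°49′26″	cyathophorum	H10(9)
P8	Saizongsi, QH	3290	N35°33′13″	E99°50′42″	cyathophorum	H5(6), H6(1)
P9	Yangshalinchang, GS	2400	N34°49′39″	E103°40′23″	cyathophorum	H7(8)
P10	Langmusi, GS	3400	N34°5′33″	E102°37′53″	cyathophorum	H8(1), H9(1)
P11	Chuanzhusi, SC	3100	N34°47′3″	E103°37′54″	cyathophorum	H12(7)
P12	Dangxiong, XZ	4269	N30°26′23′’	E91°1′50′’	spicata	H13(5)
P13	Qushui, XZ	3966	N29°14′13″	E90°37′52″	spicata	H13(17)
P14	Langkazi, XZ	4460	N28°58′49″	E90°26′36″	spicata	H13(2)
P15	Zhangnang, XZ	3567	N29°15′43″	E91°21′55″	spicata	H13(11)
P16	Gongbujiangda, XZ	4249	N29°53′54″	E92°30′38″	spicata	H13(10)
P17	Langxian, XZ	3203	N29°4′41″	E92°47′19″	spicata	H13(11)
P18	Jiacha, XZ	3203	N29°4′37″	E92°47′18′	spicata	H13(2)
P19	Langxian, XZ	3534	N28°54′01″	E93°23′51″	spicata	H14(6)
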