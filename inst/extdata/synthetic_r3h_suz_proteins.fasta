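>synthetic_ancestor synthetic R3H-SUZ family member (simulated, not a natural sequence)
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNY
KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC
LNKACCMQCCLFLTTFDQQEERQLAYDKIRSKIFTYATACISDFPNAWFRGSLHKKDVRR
YSAGMKYPFMRCGAQ
>synthetic_duplicate synthetic R3H-SUZ family member (simulated, not a natural sequence)
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNY
KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC
LNKACCMQCCLFLTTFDQQEERQLAYDKIRSKIFTYATACISDFPNAWFRGSLHKKDVRR
YSAGMKYPFMRCGAQ
>synthetic_close synthetic R3H-SUZ family member (simulated, not a natural sequence)
TFALEVTRHEFQYVRDKYFPFYCIDAKMRIEEVPFVCLDTVGGCYDCGYIFATHFPLKNY
KMDSFQFCVTGFQIIEEHLVPWSTNHMSIGAPQMKSMLLAWTQQRFRMFSTTRPGGGYRC
LNKACCCQCCLFWTTFDQKEERQLAYDKIRSKIFTYATACISPFPNAWFRNSLHKKDVRR
YSAGLKYRFMRCGYQ
>synthetic_mid synthetic R3H-SUZ family member (simulated, not a natural sequence)
TRALMVTRAEFQYVRDCEHRFYCRDAYDRLHELLFPCVDTVGGCACCYLIFAFREPLQNY
MMDSFQFHVLVFKVIEEHIVPQSTNSMSANLKVSKMMNLNWELQRGRFFRLTVCHVGYTH
LEAACCMQCCWFLTGFDFGEERQLAYDKIRSKIFTCAETKQSSFDNAIFRGSERPKILRR
LSAGQKYPFMRTGAQ
>synthetic_far synthetic R3H-SUZ family member (simulated, not a natural sequence)
QFQLLVGEHDVGYYAINAVCFYKIDDLVRIYSCMYENVDTVSGCVDCGNIFYILECLWIE
SMLSFQCVVTVFQIYELHYVPKSPIKMSIAAPDFVKYADAWVCVLAWWFSTSNKGGNYFD
LHQVCLMQCYNRPRQPWIEEENQNWQAIPRSPIFTDRWEAGSDNPNKEFCYSWMKKAVMR
CSAGHKMPMERGGAQ
>synthetic_unrelated synthetic R3H-SUZ family member (simulated, not a natural sequence)
VAGCQFAVERHQLDHFGFVKDDKPHLTCYTNGWLSALHCEYIRQTFTTSYGDQKNKQDED
HAFEINNNRKDDKHNPTRRYDPWCFKVAEVFDLHQLLKHGYIFWYMTHLNEYDASFWTMA
AVDFHGSPAWVLQLCSKTCRIDCTDMFADQGSLIKDCGCSKFTNYEGCDVTVMIHYAWSI
YVLLWPNIGHHFAWM
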