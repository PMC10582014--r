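>hallmark_MCP_synthetic synthetic stand-in gene=major_capsid_protein
MLQTGSNSGELVLGNRTTLWLYQLSLHNDATFNLIQGDITDCGGGEIATVIETGENTEFSLETAASKGAF
ERGKNYCRSGFASMCKFLLQEYLKAFHEDIRLYQAYGRPRGWTSYLGGKWAAEGLETLNVAWMAGFIFEA
LVDEGWNLRANSALQLDMIKELLRRYDHLLIPPTELDDNIGNKPTQSIGLANQVRPNTRGGGNVTPNADC
IDRVLPSQAFGHNARRRLGKKVKDLHRTDFRPSIMATELENIAEFAFAVRDQNCNAPVVEPVSCLLGENP
SAVKLVTAERAAQKATMTAKPQSREVGIMQNANQGHTFEALVITSKTNGTEGEMRAAAMASPVEAMRKEL

>hallmark_TerL_synthetic synthetic stand-in gene=terminase_large_subunit
MQMAVRKLQKLDHLVNLGILRRLFEFQRAHLELLDNLPILKVRERVSMNSLREFEQELKGGGSKARNRGI
RYKAIKNRASGIAREELGITYNYGCRFQKLKFAIDEALNINVDQDRAVFWISSPTEILDAYAVFGKGSYA
EELMEKGRVSASLMKNAAKIIEITLFDELLVQNAGGRGPIFKGTVAYKLARKIRSQKESESVGPIINATK
GTRSLLPTLCNFAGLGNRSEPKQHVFFLETIMHDGVDSSDDGSPLGEIAGAKGVGDALFTKLDEGPKFYV
ISHHDYMLVLLKIQMARLENILKGQQDWKLMKQNAFLKIAEAKTPLLKLRRVNLLVLTWLIKLQGGAMVG
GAVKEAKTLILPTDVQTPLNNFEDALVSPLLLYHKEENRRSMPHEYALRTSVGAQVLCGKLVAYEGVDVN

>hallmark_portal_synthetic synthetic stand-in gene=portal_protein
MIYQRVHIGPVPLAGPVDENGMEGVCHVKLLSTFRDLKYVHTIGALSHAGAHSGMINERQDALKFPINRW
VSLASSASRDWNIARSLELLAEVFVMSIYPVTGRLNNPLVLVLHLSVKFIFSHKLVHRQDTTLRPCTRGK
AEIVDQDRTKLSGLDVIIYLQNAMPIMSNVEAVAVNSVMPGNLIDLIRRAAELQYILLRIAEVVFNLAVG
LAPLVIYDMNRTVQEKKAADDESSDQEQRQPMQMQDMGGLEKLKSFKDLCSLIFVQEYLRIQESKNTGIA
RRWQLQFFDWDSVYKEMVAARLVMLGTHKAGMVDNVPVSTGTLTSLSFQGRAFGLSVYVPANLTNGLNDT
MQRCRGSVLEGQTCANLPIPDLKQGRSVASQKENQPIWTPGVSCTTGRYP
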