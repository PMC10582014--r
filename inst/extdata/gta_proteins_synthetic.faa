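>gta_TG_synthetic synthetic stand-in gene=TG core=true
MFLGINSAMMGILNHGDGIVFTMLVAAYFVNKELLIAGRMERSLQEMKREILGQGGSLESAAVVNAPIGA
LETQRTSYRYKVTRYLHFGGNNERRKFEVRLYMKVMLIDELPELVDEAKCAFMLLRTAGGKQRLQKEKQY
IRSDNIGYVKSKETEDKRVDAEVGTPGAEIPTPSRLELDRQARLGQLILVVIKDKSSDSRSATNTFSGTI

>gta_TAP_synthetic synthetic stand-in gene=TAP core=true
MMPRCTKVPRDPLIPSYGNIDVVVGGVSTELGASNAVAIKGMALCLTSVNFLPQQSMELTFKEDAYWFGI
PETDAPRGSSVIKNKRMWRHELLVMLYEPQVVMKQRLCGRATILGRSNSDPCSVKVLMGLPYTRLEFDFK
VPSFSRNTAVIGSRQQYTITAEARRIMNVNSYRLGNFVGYSPGVEIPRLA
>gta_TTP_synthetic synthetic stand-in gene=TTP core=true
MPKAADNKAGRYASANSLPTVSKETITIEKADIQSVILMVGLAELNISSEVLQQNDLASFDILPSYGPAL
ELNYKENADPWIIIQSNAFHNKTYLEGATYEQDDQSAELLVLQHKTWAQCWVARLVKPPLDAMNSIGYSE
NARVFMALPDPDGEWHLETM
>gta_MTP_synthetic synthetic stand-in gene=MTP core=true
MTVRTKITSTGGECTQFQIDAETVTIEDAHLLSARELKILGELFDSGLLSTPPLGSPLGYTSEAHHDPSN
QIILKKRKKAGIYGKEVMWICDKLIFLGFWLSIPPRLVALCTGDTDTPRGGRAKTLALPCTLQPGASKGV
ITLAEKKPIGKPHQALRAKIGAIPSVGDMMRLGLRARETVSSVQELLEKVIVVLTGAIIRGVDDVRVKIT
DAKAPRGLGKISNPIRMHSAISGIGMAMDL
>gta_HTJ_synthetic synthetic stand-in gene=HTJ core=true
MGDFREKVIVAKVVSAISALIAPLEWSMDLSKNKWWEGAAMILRSPRLHLHGDRLVRLISDWRLNRKCNQ
TSWSRELVDLIAAFVRALGAIVPQSSVHGGGKNAYADASGLTRAGVDDKRTNSYEAIVIN
>gta_GP6_synthetic synthetic stand-in gene=GP6 core=true
MENNTWEILRGAPFANTFPVASWPVKMAGYSSPPEQFGSAKGGLSKKHKYVDVLLARTMPYNAYEEIRNR
STRSKLQAVTQADVAQTVTVGLQSMLPWFAEKTAPDGHLSKFVCNPQLVDAAFRGSNFSDQAYYVDYGDE
SLPHNVMESISWYTSLISNRLKNLIEARPMKQQLASEIGR
>gta_MCP_synthetic synthetic stand-in gene=MCP core=true
MVTLIGCNALGEVLGSMGMTRQPNINLFLVQRGTTDYAHTDELRVAKSGHGRRKALNTVILSHNEVRQNY
FQGNQPVPINYPRTMLQYPFIQKYLEGKIKLVQENPNATVGDHLHEQYKVAESDFAAQTLYTVRLPRGQS
MSLVIQGSQSNISIEHRRSGGTVHRAVNHNRAGEGTMLLKGYLGGTPVNATSLAGEHNPMISRRPITTSA
LAVLRKFALFASDPDQDFHSAVCCGQTQLGVDADPMHSMIHENLKETGISLLHGGCMYFQMKSDDLTKEA
DNGDLEVENAAVYQKVQNDIKFRRLIEDQEVMRVLSKSTIGAPRQEAGCA
>gta_Prot_synthetic synthetic stand-in gene=Prot core=true
MLSLFVPLKSPFATLAVRSATLDVLLAITEVFDGIELKFIPLNSQTVEGKFRMQVASPGTQGKAAIYGQK
KMTSSANRKVAKQLGQNPVHLSRYTFEDDSGVTGHEIDLRLTKAERMATHVVVDSYWLVASGKMARPLNE
GDYILYSFKLGLLNDVLQVGLLQLLNTDIAWMSTESTLTYRQCKNVRNGITQKQQQVVFIGQITSAIEAM
KERNGVPTIQ
>gta_PPP_synthetic synthetic stand-in gene=PPP core=true
MNFMLPAKIPVTRLSFDNNFSTPRADYILKAAKTNRQLNRLEIAYPSDGIVLVLRPESDKWRKSLYVSGY
KKPMGIINPCGTLSKFQSNKGCPELDKKYKTRKLANVLRTNLNRLTVLQHINIVDLTFYNTEEISQQNRN
EIDKGVNAVAQAHVPKGACETQQIKVRLSDVKSCLVYNPEPLNKKSEIKVLRMAKEVMNVTPNTDLLGLK
NGNDGTAQVLQWNLDMRSRARLSGKPGKSLKQREKNEVSLGYLARRRGITGDNGIVFGYVTVKSKGSFLK
ARMQCSAQIVKRPLEAAPKPESAIKPGLDNDLHAQESHVSPHGVGNIAFVLFIQTGQKDF
>gta_MBP_synthetic synthetic stand-in gene=MBP core=true
MKSRASIIIGFGLLLKKSWNVRGNDNSEYSNELMIEHVKHDTLLNKNTAFGDPEKMWWQPQDQRVAQHII
RDRYDALPLVVAFSVDAQSAPSVSGAQFTIVELGTGFAPNFYPFVLNILGESAKLSRAVTIGVKAKASYS
VIAEYARNNR
>gta_AT_synthetic synthetic stand-in gene=AT core=false
MWRPYSIHRQRGALALTVYPELVAPALLIAYTCYDKINVNSGLKSVKPNFGVVGQREIPSPVGPSSVSGS
WAFSDYITVVSALRSCGRVHAKLMANVLTVAATGATSGGLIAPNLLREDPTDNLTNKYEKVGQLFTKAIS

>gta_Pept_synthetic synthetic stand-in gene=Pept core=false
MTGPLLGSNLVEGGQLYYVKAMNRIPTGWAVADDPSNTNPDKQGPPKGEQKTPSYSVQWGVGCGRSSNDL
SAVGFSFVLEKLDFLQGSIGHLAGHIRKTFGKRGEAWIAEVLLMDLYNKADKHSLHAALLCIHVRRCGPY
ATKFMGYNSHGEDQAAITIRLSAEVDGPSK
>gta_TMP_synthetic synthetic stand-in gene=TMP core=false
MIADMQYCANDPHQPILYMPAVYKTADQKSSLGATYELTPNVGGNALGLKRQLGIAEKESEIRYMTLVVG
DVRASVRDAIQWGPRENINVSVTALFNLEIIKMWDALKDLAQTVNQPVDGGWREDPEFGLLGQLVVRAPS
ADMEVVTRIKYDLLALSTRGSTQESQLILPAKTDRVDDLMFTGNSFKYIKVDTVAAGLPAEVKFFFEKEM
KAGTLPEGECIKSFCPCFAVKNTKFPDNNVARLFFVIIANVISVDSNGAALERRHKIRGLKVYTMSSKAY
IQEVSPSVKARVLQTKPRAL
>gta_HypA_synthetic synthetic stand-in gene=HypA core=false
MGWGDKHQEAVISMPSAFDFDDYGNFNVKHFGETAPLIKFNEVVYQNGRYMRFSVIMKNRLMRFLFLSVI
KFGKKIIRVIALAQYTPAAS
>gta_HypB_synthetic synthetic stand-in gene=HypB core=false
MRGDTPIIGLKASIVVLNQQMDSGETPGPRGSDTSDSVVILYNSSGAQARIELEMKLALHGPLVWGLIFN
SQVLDGWLLVWEESSRCTAFGADAMAKKRMTDLNPAWRAN
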